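cm29 <- coded_matrix(canonical_design())

test_that("noiseless responses are recovered to numerical precision", {
  set.seed(2)
  beta <- rnorm(10, sd = 2)
  y <- drop(cm29 %*% beta)
  fit <- fit_quadratic(y, cm29)
  expect_lt(max(abs(coef(fit) - beta)), 1e-8)
  expect_equal(fit$r2, 1)
  expect_equal(fit$df_total, 28L)
  expect_equal(fit$df_model, 9L)
  expect_equal(fit$df_residual, 19L)
})

test_that("a constant response gives an intercept-only model", {
  fit <- fit_quadratic(rep(4.2, nrow(cm29)), cm29)
  expect_equal(unname(coef(fit)["b0"]), 4.2)
  expect_lt(max(abs(coef(fit)[-1])), 1e-10)
})

test_that("insufficient data and rank deficiency are rejected", {
  expect_error(fit_quadratic(rnorm(10), cm29[1:10, ]), "observations")
  bad <- cm29
  bad[, "X2"] <- bad[, "X1"]
  expect_error(fit_quadratic(rnorm(29), bad), "rank deficient")
})

test_that("residuals are orthogonal to every design column", {
  set.seed(3)
  fit <- fit_quadratic(drop(cm29 %*% rnorm(10)) + rnorm(29), cm29)
  ip <- abs(crossprod(cm29, residuals(fit)))
  expect_lt(max(ip), 1e-8 * sum(abs(residuals(fit))))
})

test_that("adding a constant to the response only shifts the intercept", {
  set.seed(5)
  y <- drop(cm29 %*% rnorm(10)) + rnorm(29, sd = 0.3)
  f1 <- fit_quadratic(y, cm29)
  f2 <- fit_quadratic(y + 7, cm29)
  expect_equal(unname(coef(f2)["b0"] - coef(f1)["b0"]), 7)
  expect_equal(coef(f2)[-1], coef(f1)[-1])
})

test_that("r2_adj never exceeds r2, with equality only at r2 = 1", {
  set.seed(6)
  for (i in 1:25) {
    y <- drop(cm29 %*% rnorm(10)) + rnorm(29, sd = runif(1, 0.1, 3))
    fit <- fit_quadratic(y, cm29)
    expect_lte(fit$r2_adj, fit$r2)
    expect_true(fit$r2 < 1 || fit$r2_adj == fit$r2)
    # closed form
    expect_equal(fit$r2_adj, 1 - (1 - fit$r2) * 28 / 19)
  }
})

test_that("partial F-tests decompose a noiseless single-factor response", {
  y <- drop(cm29 %*% c(1, 0, 0, 2.5, rep(0, 6)))  # depends only on X3
  fit <- fit_quadratic(y, cm29)
  expect_warning(a <- anova(fit), "perfect fit")
  expect_true(a$significant[a$term == "b3"])
  expect_equal(a$p[a$term == "b3"], 0)
  others <- a[a$term != "b3", ]
  expect_lt(max(others$ss), 1e-8)
  expect_false(any(others$significant))
})

test_that("a strong effect at realistic noise is detected at tiny p", {
  set.seed(7)
  sigma <- 0.5
  y <- drop(cm29 %*% c(0, 0, 0, 5 * sigma, rep(0, 6))) + rnorm(29, sd = sigma)
  a <- anova(fit_quadratic(y, cm29))
  expect_lt(a$p[a$term == "b3"], 1e-6)
})

test_that("partial F equals the squared coefficient t-statistic", {
  set.seed(8)
  y <- drop(cm29 %*% rnorm(10)) + rnorm(29)
  fit <- fit_quadratic(y, cm29)
  a <- anova(fit)
  tt <- summary(fit$lm)$coefficients[-1, "t value"]
  expect_equal(a$f, unname(tt^2), tolerance = 1e-10)
})

test_that("prediction evaluates the fitted surface", {
  y <- drop(cm29 %*% c(2, 0, 0, 0, 0, 0, 1.5, 0, 0, 0))  # 2 + 1.5 X3^2
  fit <- fit_quadratic(y, cm29)
  expect_equal(unname(predict(fit, newdata = cbind(X1 = 0, X2 = 0, X3 = 0))),
               2, tolerance = 1e-9)
  # symmetric in X3
  nd <- matrix(c(0, 0, -1, 0, 0, 1), 2, 3, byrow = TRUE,
               dimnames = list(NULL, c("X1", "X2", "X3")))
  p <- predict(fit, newdata = nd)
  expect_equal(p[1], p[2])
  expect_warning(predict(fit, newdata = cbind(X1 = 2, X2 = 0, X3 = 0)),
                 "extrapolation")
  g <- predict(fit, grid_n = 5, fix = c(X1 = 0, X2 = 0))
  expect_equal(nrow(g), 5L)
  expect_equal(g$predicted, 2 + 1.5 * g$X3^2, tolerance = 1e-9)
})

test_that("a negative quadratic CHIR term puts the fitted peak inside the range", {
  sc <- wnt_dominant_scenario(noise_sd = 0, seed = 1)
  expr <- relative_expression(generate_ct(sc))
  L <- log2(expr[rownames(cm29), "NKX2.5"])
  fit <- fit_quadratic(L, cm29, name = "NKX2.5 log2 expression")
  b <- coef(fit)
  vertex <- -b["b3"] / (2 * b["b33"])
  expect_lt(b["b33"], 0)
  expect_gt(vertex, -1)
  expect_lt(vertex, 1)
})

test_that("fit_scores fits one model per score with aligned rows", {
  set.seed(10)
  scores <- matrix(rnorm(29 * 5), 29, 5,
                   dimnames = list(sample(rownames(cm29)),  # shuffled rows
                                   colnames(default_weights())))
  fits <- fit_scores(scores, cm29)
  expect_named(fits, colnames(scores))
  f <- fit_quadratic(scores[rownames(cm29), "Ectoderm"], cm29)
  expect_equal(coef(fits$Ectoderm), coef(f))
  expect_error(fit_scores(scores[1:5, ], cm29), "lacks observation")
})

test_that("summary and simulate methods are well-formed", {
  set.seed(12)
  fit <- fit_quadratic(drop(cm29 %*% rnorm(10)) + rnorm(29), cm29,
                       name = "demo")
  s <- summary(fit)
  expect_s3_class(s$anova, "anova_quadfit")
  expect_output(print(s), "R2")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(29L, 3L))
})
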