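test_that("Pearson correlation distance matches hand computation", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 4), c = c(2, 4, 6),
             d = c(3, 2, 1))
  d <- as.matrix(pearson_distance(m))
  expect_equal(d["a", "b"], 1 - 9 / sqrt(84), tolerance = 1e-12)
  expect_equal(d["a", "c"], 0)        # proportional rows
  expect_equal(d["a", "d"], 2)        # exactly anti-correlated
  expect_equal(diag(d), c(a = 0, b = 0, c = 0, d = 0))
  expect_true(all(d >= 0 & d <= 2))
})

test_that("correlation distance is invariant to per-sample affine maps", {
  set.seed(21)
  m <- matrix(rnorm(30), 6, 5)
  m2 <- m * runif(6, 0.5, 3) + rnorm(6)   # row-wise a*x + b, a > 0
  expect_equal(pearson_distance(m), pearson_distance(m2),
               tolerance = 1e-12)
})

test_that("constant rows and single-variable input are rejected", {
  expect_error(pearson_distance(rbind(a = c(1, 1, 1), b = 1:3)),
               "constant row.*a")
  expect_error(pearson_distance(cbind(1:3)), "at least 2 variables")
})

test_that("UPGMA reproduces hand-computed merges", {
  d <- stats::as.dist(rbind(c(0, 0.1, 0.5), c(0.1, 0, 0.5),
                            c(0.5, 0.5, 0)))
  h <- upgma_cluster(d)
  expect_equal(h$height, c(0.1, 0.5))
  # two samples: single merge at their distance
  d2 <- stats::dist(rbind(a = c(0, 0), b = c(3, 4)))
  expect_equal(upgma_cluster(d2)$height, 5)
})

test_that("UPGMA merge heights equal the brute-force cross-pair oracle", {
  set.seed(22)
  for (i in 1:25) {
    m <- matrix(rnorm(6 * 4), 6, 4)
    d <- stats::dist(m)
    h <- upgma_cluster(d)
    expect_equal(sort(h$height), upgma_oracle_heights(d),
                 tolerance = 1e-12)
  }
})

test_that("UPGMA is equivariant under sample relabeling", {
  set.seed(23)
  m <- matrix(rnorm(6 * 5), 6, 5,
              dimnames = list(paste0("s", 1:6), NULL))
  d <- stats::dist(m)
  for (i in 1:10) {
    perm <- sample(6)
    dp <- stats::dist(m[perm, ])
    expect_equal(sort(upgma_cluster(dp)$height),
                 sort(upgma_cluster(d)$height), tolerance = 1e-12)
    cl <- cut_clusters(upgma_cluster(d), 3)
    clp <- cut_clusters(upgma_cluster(dp), 3)
    expect_equal(rand_index(cl[rownames(m)[perm]], clp), 1)
  }
})

test_that("cluster cuts undo the last merges", {
  set.seed(24)
  d <- stats::dist(matrix(rnorm(12), 6, 2))
  h <- upgma_cluster(d)
  expect_equal(unname(cut_clusters(h, 1)), rep(1L, 6))
  expect_equal(sort(unname(cut_clusters(h, 6))), 1:6)
  expect_error(cut_clusters(h, 0), "between 1 and")
  expect_error(cut_clusters(h, 7), "between 1 and")
})

test_that("PCA variance fractions match a direct eigen-decomposition", {
  m <- rbind(c(1, 2), c(4, 3), c(2, 8))
  p <- pca_svd(m)
  ev <- eigen(stats::cov(m))$values
  expect_equal(p$explained, ev / sum(ev), tolerance = 1e-10)
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
})

test_that("a rank-1 matrix loads entirely on PC1", {
  u <- 1:5
  m <- outer(u, c(2, -1, 0.5))
  p <- pca_svd(m)
  expect_equal(p$explained[1], 1, tolerance = 1e-12)
})

test_that("PCA on complete data equals direct SVD; loadings orthonormal", {
  set.seed(25)
  m <- matrix(rnorm(40), 10, 4)
  p <- pca_svd(m)
  expect_equal(p$iterations, 0L)
  sv <- svd(scale(m, center = TRUE, scale = FALSE))
  expect_equal(abs(p$scores), abs(sweep(sv$u[, 1:4], 2, sv$d[1:4], "*")),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(crossprod(p$loadings), diag(4), ignore_attr = TRUE,
               tolerance = 1e-10)
  # reconstruction: scores %*% t(loadings) gives back the centered data
  expect_equal(p$scores %*% t(p$loadings),
               scale(m, center = TRUE, scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("iterative SVD imputation recovers sparse missing entries", {
  set.seed(26)
  u <- rnorm(12); v <- rnorm(5)
  m <- outer(u, v) + matrix(rnorm(60, sd = 0.01), 12, 5)
  miss <- cbind(c(2, 7, 11), c(1, 3, 5))
  m_na <- m
  m_na[miss] <- NA
  p <- pca_svd(m_na, rank = 1)
  expect_true(p$converged)
  ctr <- attr(scale(m, center = TRUE, scale = FALSE), "scaled:center")
  imputed <- p$completed[miss]
  truth <- (m - matrix(colMeans(m), 12, 5, byrow = TRUE))[miss]
  expect_lt(max(abs(imputed - truth)), 0.2)
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)
})

test_that("over-missing rows or columns are rejected", {
  m <- matrix(rnorm(20), 4, 5)
  m[1, 1:3] <- NA
  expect_error(pca_svd(m), "half or more missing")
})

test_that("dendrograms export as Newick", {
  skip_if_not_installed("ape")
  d <- stats::dist(matrix(rnorm(12), 6, 2))
  h <- upgma_cluster(d)
  f <- tempfile(fileext = ".nwk")
  write_newick(h, f)
  tr <- ape::read.tree(f)
  expect_equal(length(tr$tip.label), 6L)
})
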