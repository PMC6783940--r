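test_that("min-max normalization maps gene extremes to 0 and 1", {
  m <- cbind(G1 = c(2, 4, 6), G2 = c(1, 10, 100))
  rownames(m) <- paste0("s", 1:3)
  n <- minmax_normalize(m)
  expect_equal(unname(n[, "G1"]), c(0, 0.5, 1))
  expect_equal(unname(n[, "G2"]), c(0, 9 / 99, 1))
  # idempotent on a column already spanning {0, 1}
  expect_equal(minmax_normalize(n), n)
})

test_that("normalization is invariant to per-gene positive affine rescaling", {
  set.seed(4)
  m <- matrix(rexp(60), 12, 5, dimnames = list(paste0("s", 1:12),
                                               paste0("g", 1:5)))
  m2 <- sweep(sweep(m, 2, runif(5, 0.5, 4), "*"), 2, rnorm(5), "+")
  expect_equal(minmax_normalize(m), minmax_normalize(m2),
               ignore_attr = TRUE)
})

test_that("degenerate genes error by default, map to 0 on request", {
  m <- cbind(G1 = c(1, 1, 1), G2 = c(0, 1, 2))
  expect_error(minmax_normalize(m), "constant.*G1")
  expect_warning(n <- minmax_normalize(m, degenerate = "zero"), "G1")
  expect_equal(unname(n[, "G1"]), c(0, 0, 0))
})

test_that("a restricted cohort sets the extremes, other rows extrapolate", {
  m <- cbind(G = c(1, 3, 5))
  rownames(m) <- c("a", "b", "ctrl")
  n <- minmax_normalize(m, cohort = c("a", "b"))
  expect_equal(unname(n[, "G"]), c(0, 1, 2))
  expect_error(minmax_normalize(m, cohort = c("a", "zz")), "zz")
})

test_that("panels average member genes; missing genes are named", {
  norm <- matrix(0.5, 2, 11, dimnames = list(
    c("s1", "s2"), unlist(default_panels(), use.names = FALSE)))
  norm["s1", c("FGF5", "PAX6", "P75")] <- c(0.1, 0.2, 0.6)
  p <- compute_panels(norm)
  expect_equal(p["s1", "Ectoderm"], 0.3)
  expect_equal(p["s2", "Mesendoderm"], 0.5)
  expect_error(compute_panels(norm[, -3, drop = FALSE]),
               "FGF5.*Ectoderm")
})

test_that("gene matching is case-insensitive and alias-aware", {
  genes <- c("oct4", "Nanog", "FGF5", "PAX6", "NGFR", "MIXL1", "TBXT",
             "NKX2.5", "MESP1", "SOX17", "PDX1")
  norm <- matrix(runif(22), 2, 11, dimnames = list(c("a", "b"), genes))
  p <- compute_panels(norm)
  expect_equal(p[, "Mesendoderm"],
               rowMeans(norm[, c("MIXL1", "TBXT")]))
  expect_equal(p[, "Ectoderm"],
               rowMeans(norm[, c("FGF5", "PAX6", "NGFR")]))
})

test_that("default weight rows sum to zero and reproduce the score formulas", {
  w <- default_weights()
  expect_equal(unname(rowSums(w)), rep(0, 5))
  # unit pluripotent panel, all others zero
  pan <- matrix(c(1, 0, 0, 0, 0), 1,
                dimnames = list("s", colnames(w)))
  expect_equal(compute_scores(pan)["s", "Pluripotency"], 1.5)
  expect_equal(compute_scores(pan)["s", "Mesoderm"], -1)
  # uniform panels give all-zero scores
  pan1 <- matrix(1, 1, 5, dimnames = list("s", colnames(w)))
  expect_equal(unname(compute_scores(pan1)["s", ]), rep(0, 5))
  pan0 <- matrix(0, 1, 5, dimnames = list("s", colnames(w)))
  expect_equal(unname(compute_scores(pan0)["s", ]), rep(0, 5))
})

test_that("scores are linear in the panel values", {
  set.seed(9)
  p1 <- matrix(runif(10), 2, 5,
               dimnames = list(c("a", "b"), colnames(default_weights())))
  p2 <- matrix(runif(10), 2, 5, dimnames = dimnames(p1))
  s <- compute_scores(3 * p1 - 2 * p2)
  expect_equal(unclass(s),
               unclass(3 * compute_scores(p1) - 2 * compute_scores(p2)),
               ignore_attr = TRUE)
})

test_that("panel/weight mismatches are configuration errors", {
  pan <- matrix(1, 1, 5, dimnames = list("s", paste0("P", 1:5)))
  expect_error(compute_scores(pan), "do not match")
})

test_that("the lineage assignment is the argmax score", {
  pan <- diag(5)
  dimnames(pan) <- list(paste0("s", 1:5), colnames(default_weights()))
  sc <- compute_scores(pan)
  expect_equal(attr(sc, "lineage"),
               c("Pluripotency", "Ectoderm", "Mesendoderm", "Mesoderm",
                 "Endoderm"))
})

test_that("bundled panel and weight YAMLs match the built-in defaults", {
  p <- read_panels_yaml(system.file("extdata", "panels.yaml",
                                    package = "stemfactor"))
  w <- read_weights_yaml(system.file("extdata", "weights.yaml",
                                     package = "stemfactor"))
  expect_equal(p, default_panels())
  expect_equal(w, default_weights())
})
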