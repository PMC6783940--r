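#' Pearson correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation between two
#' samples' variable vectors (rows). Values lie in `[0, 2]`; identical
#' profiles are at distance 0, perfectly anti-correlated ones at 2.
#'
#' @param m Sample x variable numeric matrix with at least 2 variables; no
#'   row may be constant (correlation undefined).
#' @return A `stats::dist` object over the rows.
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
#' round(as.matrix(pearson_distance(m)), 6)
#' @export
pearson_distance <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 variables per sample",
                         call. = FALSE)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    stop("constant row(s) make the correlation undefined: ",
         paste(rownames(m)[sds == 0], collapse = ", "), call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(t(m)))
  attr(d, "method") <- "pearson"
  d
}

#' UPGMA (average linkage) hierarchical clustering
#'
#' Agglomerative clustering where the distance between two clusters is the
#' unweighted arithmetic mean of all cross-pair distances between their
#' members.
#'
#' @param d A `stats::dist` object (e.g. from [pearson_distance()]) over at
#'   least 2 items.
#' @return A `stats::hclust` object (`method = "average"`), usable with
#'   [cut_clusters()], [stats::cutree()] and [write_newick()].
#' @export
upgma_cluster <- function(d) {
  if (!inherits(d, "dist")) stop("'d' must be a stats::dist object",
                                 call. = FALSE)
  if (attr(d, "Size") < 2L) stop("need at least 2 samples to cluster",
                                 call. = FALSE)
  stats::hclust(d, method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges of the clustering.
#'
#' @param dend An `hclust` object.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector: sample label to cluster id.
#' @export
cut_clusters <- function(dend, k) {
  n <- length(dend$order)
  if (k < 1L || k > n) stop("'k' must be between 1 and ", n, call. = FALSE)
  stats::cutree(dend, k = k)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths reflect merge heights (ultrametric tree). Requires the
#' \pkg{ape} package.
#'
#' @param dend An `hclust` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dend, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("package 'ape' is required for Newick export", call. = FALSE)
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}

#' PCA by singular value decomposition with iterative imputation
#'
#' Columns are centered (and optionally unit-variance scaled); missing
#' entries, if any, are filled by iterative low-rank SVD reconstruction
#' (initialize missing cells at the column mean, i.e. 0 after centering;
#' alternate rank-`rank` SVD reconstruction and re-imputation of the missing
#' cells until the imputed values change by less than `tol` in RMS, or
#' `max_iter` is reached). Components are then taken from the SVD of the
#' completed centered matrix; the variance fraction of component `k` is
#' `sigma_k^2 / sum(sigma^2)` over the singular values.
#'
#' On a complete matrix the imputation loop is a no-op and the result equals
#' a direct SVD/eigen principal component analysis.
#'
#' @param m Sample x variable numeric matrix, possibly with `NA` entries
#'   (each row and column must be less than half missing).
#' @param center Center columns (default `TRUE`).
#' @param scale. Unit-variance scale columns (default `FALSE`).
#' @param rank Rank used during imputation (default 2).
#' @param tol Convergence tolerance on the RMS change of imputed values
#'   (default `1e-6`).
#' @param max_iter Maximum imputation iterations (default 100).
#' @return Object of class `"pca_svd"`: list with `scores` (sample x
#'   component), `loadings` (variable x component, orthonormal columns),
#'   `explained` (variance fractions, non-increasing, summing to 1),
#'   `completed` (the imputed centered/scaled matrix), `converged`,
#'   `iterations`.
#' @examples
#' m <- matrix(rnorm(40), 10, 4)
#' p <- pca_svd(m)
#' sum(p$explained)  # 1
#' @export
pca_svd <- function(m, center = TRUE, scale. = FALSE, rank = 2,
                    tol = 1e-6, max_iter = 100) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 samples and 2 variables", call. = FALSE)
  na <- is.na(m)
  if (any(rowMeans(na) >= 0.5) || any(colMeans(na) >= 0.5))
    stop("a row or column is half or more missing; cannot impute",
         call. = FALSE)

  ctr <- if (center) colMeans(m, na.rm = TRUE) else rep(0, ncol(m))
  x <- sweep(m, 2, ctr, "-")
  if (scale.) {
    s <- apply(x, 2, stats::sd, na.rm = TRUE)
    if (any(s == 0)) stop("constant column(s) cannot be unit-variance scaled",
                          call. = FALSE)
    x <- sweep(x, 2, s, "/")
  }

  converged <- TRUE
  iterations <- 0L
  if (any(na)) {
    rank <- min(rank, nrow(x) - 1L, ncol(x))
    x[na] <- 0  # column mean after centering
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      sv <- svd(x, nu = rank, nv = rank)
      recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
      delta <- sqrt(mean((x[na] - recon[na])^2))
      x[na] <- recon[na]
      iterations <- it
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning("SVD imputation did not converge in ", max_iter,
              " iterations; using last iterate")
    # re-center after imputation so the completed matrix has zero column means
    if (center) {
      ctr2 <- colMeans(x)
      x <- sweep(x, 2, ctr2, "-")
    }
  }

  sv <- svd(x)
  ncomp <- min(nrow(x) - as.integer(center), ncol(x))
  d2 <- sv$d[seq_len(ncomp)]^2
  scores <- sweep(sv$u[, seq_len(ncomp), drop = FALSE], 2,
                  sv$d[seq_len(ncomp)], "*")
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(ncomp)))
  dimnames(loadings) <- list(colnames(m), paste0("PC", seq_len(ncomp)))

  structure(list(scores = scores, loadings = loadings,
                 explained = d2 / sum(sv$d^2), completed = x,
                 center = center, scale = scale.,
                 converged = converged, iterations = iterations),
            class = "pca_svd")
}

#' @export
print.pca_svd <- function(x, ...) {
  cat("PCA (SVD", if (x$iterations > 0) " with iterative imputation", "):\n",
      sep = "")
  ev <- round(100 * x$explained, 1)
  cat(paste0(names(ev) <- NULL, "PC", seq_along(ev), ": ", ev, "%",
             collapse = "  "), "\n")
  invisible(x)
}

# plain Rand index between two partitions of the same items
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}
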