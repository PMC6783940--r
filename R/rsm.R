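#' Fit a full quadratic response-surface model
#'
#' Ordinary least squares fit of the full quadratic model in the coded
#' factor levels:
#'
#' \deqn{Y = \beta_0 + \sum_i \beta_i X_i + \sum_i \beta_{ii} X_i^2 +
#'   \sum_{i<j} \beta_{ij} X_i X_j + \epsilon}
#'
#' For three factors this is a 10-parameter model (intercept, 3 linear,
#' 3 quadratic, 3 interaction terms). The solve goes through a QR
#' factorization (via [stats::lm()]), never the normal equations, so a
#' noiseless response generated from known coefficients is recovered to
#' numerical precision.
#'
#' @param response Numeric vector of per-observation response values (one
#'   score), ordered as the rows of `design`; or a named vector matched
#'   against the design's observation labels.
#' @param design A coded design matrix from [coded_matrix()], or a
#'   [factorial_design()] (coded with defaults).
#' @param name Response name carried into printouts (default deparsed).
#' @return An object of class `"quadfit"`: list with `coefficients` (the 10
#'   betas, named `b0, b1, b2, b3, b11, b22, b33, b12, b13, b23`),
#'   `residuals`, `fitted`, `sigma2` (residual variance), `df_total`,
#'   `df_model`, `df_residual`, `r2`, `r2_adj`, the underlying `lm` fit and
#'   the design matrix.
#' @examples
#' cm <- coded_matrix(canonical_design())
#' y <- 2 + 3 * cm[, "X3"] - 1.5 * cm[, "X3.2"]
#' fit <- fit_quadratic(y, cm, name = "toy")
#' coef(fit)[c("b0", "b3", "b33")]
#' @export
fit_quadratic <- function(response, design, name = NULL) {
  if (inherits(design, "factorial_design")) design <- coded_matrix(design)
  stopifnot(is.matrix(design), colnames(design)[1L] == "b0")
  if (is.null(name))
    name <- if (!is.null(attr(response, "response_name")))
      attr(response, "response_name") else "response"
  y <- as.numeric(response)
  if (!is.null(names(response)) && !is.null(rownames(design))) {
    if (setequal(names(response), rownames(design)) &&
        !anyDuplicated(rownames(design)))
      y <- as.numeric(response[rownames(design)])
  }
  n <- length(y)
  p <- ncol(design)
  if (n != nrow(design))
    stop("response length (", n, ") does not match design rows (",
         nrow(design), ")", call. = FALSE)
  if (n <= p)
    stop("need more than ", p, " observations to fit the ", p,
         "-parameter model (got ", n, ")", call. = FALSE)
  if (qr(design)$rank < p) {
    qd <- qr(design)
    drop_cols <- colnames(design)[qd$pivot[-seq_len(qd$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }

  dat <- as.data.frame(design[, -1, drop = FALSE])
  dat$.y <- y
  lmfit <- stats::lm(.y ~ ., data = dat)

  beta <- stats::coef(lmfit)
  names(beta) <- term_labels(colnames(design))
  res <- stats::residuals(lmfit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  df_res <- n - p

  structure(list(
    name = name,
    coefficients = beta,
    residuals = res,
    fitted = stats::fitted(lmfit),
    sigma2 = ss_res / df_res,
    df_total = n - 1L, df_model = p - 1L, df_residual = df_res,
    r2 = r2, r2_adj = r2_adj,
    lm = lmfit, design = design
  ), class = "quadfit")
}

# "b0, X1, X2, X3, X1.2, ..., X1.X2, ..." -> "b0, b1, b2, b3, b11, ..., b12, ..."
term_labels <- function(design_cols) {
  lab <- design_cols
  lab <- sub("^X(\\d+)\\.2$", "b\\1\\1", lab)
  lab <- sub("^X(\\d+)\\.X(\\d+)$", "b\\1\\2", lab)
  lab <- sub("^X(\\d+)$", "b\\1", lab)
  lab
}

#' @export
coef.quadfit <- function(object, ...) object$coefficients

#' @export
residuals.quadfit <- function(object, ...) object$residuals

#' @export
fitted.quadfit <- function(object, ...) object$fitted

#' @export
print.quadfit <- function(x, digits = 4, ...) {
  cat(sprintf("Full quadratic response-surface model: %s\n", x$name))
  cat(sprintf("n = %d, df(total) = %d, df(residual) = %d\n",
              x$df_total + 1L, x$df_total, x$df_residual))
  cat(sprintf("R2 = %.4f, R2-adj = %.4f\n", x$r2, x$r2_adj))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Per-term ANOVA of a quadratic response-surface fit
#'
#' Partial (Type III) single-degree-of-freedom F-tests: each non-intercept
#' term is tested by comparing the full 10-parameter model against the model
#' with that one column removed, with the F statistic referred to an
#' F(1, df_residual) distribution. Terms with p < alpha are flagged
#' significant. The model is never refined by dropping terms, and no
#' multiplicity correction is applied across terms or responses.
#'
#' @param object A `"quadfit"`.
#' @param alpha Significance level for the flag (default 0.05).
#' @param ... Unused.
#' @return A data.frame of class `"anova_quadfit"` with one row per
#'   non-intercept term: `term`, `ss` (partial sum of squares), `df`, `f`,
#'   `p`, `significant`.
#' @export
anova.quadfit <- function(object, alpha = 0.05, ...) {
  X <- object$design
  y <- object$fitted + object$residuals
  rss_full <- sum(object$residuals^2)
  terms <- colnames(X)[-1L]
  ss <- f <- p <- numeric(length(terms))
  perfect <- object$sigma2 <= .Machine$double.eps * max(1, stats::var(y))
  ss_tol <- .Machine$double.eps^0.5 * max(1, sum(y^2))
  for (i in seq_along(terms)) {
    Xr <- X[, setdiff(colnames(X), terms[i]), drop = FALSE]
    fit_r <- stats::lm.fit(Xr, y)
    ss[i] <- sum(fit_r$residuals^2) - rss_full
    if (perfect) {
      f[i] <- if (ss[i] > ss_tol) Inf else 0
      p[i] <- if (ss[i] > ss_tol) 0 else 1
    } else {
      f[i] <- ss[i] / object$sigma2
      p[i] <- stats::pf(f[i], 1, object$df_residual, lower.tail = FALSE)
    }
  }
  if (perfect)
    warning("perfect fit (zero residual variance); p-values reported as 0 ",
            "for terms with nonzero sum of squares")
  out <- data.frame(term = term_labels(terms), ss = ss, df = 1L, f = f,
                    p = p, significant = p < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("anova_quadfit", "data.frame")
  attr(out, "response") <- object$name
  attr(out, "df_residual") <- object$df_residual
  out
}

#' @export
print.anova_quadfit <- function(x, digits = 4, ...) {
  cat(sprintf("Per-term partial F-tests (%s), F(1, %d):\n",
              attr(x, "response"), attr(x, "df_residual")))
  y <- as.data.frame(x)
  y$ss <- signif(y$ss, digits); y$f <- signif(y$f, digits)
  y$p <- signif(y$p, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
summary.quadfit <- function(object, ...) {
  structure(list(fit = object, anova = anova(object)),
            class = "summary.quadfit")
}

#' @export
print.summary.quadfit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$anova)
  invisible(x)
}

#' Predict the fitted response surface
#'
#' Evaluates the fitted quadratic surface at supplied coded factor levels,
#' or over a regular grid. Points beyond the coded range `[-1, 1]` are
#' allowed with an extrapolation warning.
#'
#' @param object A `"quadfit"`.
#' @param newdata Matrix or data.frame of coded linear levels with one
#'   column per factor (named `X1`, `X2`, `X3`, ...). If `NULL`, a full grid
#'   is built from `grid_n` points per free factor.
#' @param grid_n Grid resolution per factor when `newdata` is `NULL`
#'   (default 11).
#' @param fix Optional named numeric vector fixing some factors at coded
#'   values while the rest vary over the grid (surface slicing).
#' @param ... Unused.
#' @return If `newdata` is given: numeric vector of predictions. Otherwise a
#'   data.frame with the grid coordinates and a `predicted` column.
#' @examples
#' cm <- coded_matrix(canonical_design())
#' fit <- fit_quadratic(2 - cm[, "X3.2"], cm)
#' predict(fit, newdata = cbind(X1 = 0, X2 = 0, X3 = 0))  # 2
#' @export
predict.quadfit <- function(object, newdata = NULL, grid_n = 11,
                            fix = NULL, ...) {
  k <- sum(grepl("^X\\d+$", colnames(object$design)))
  lin <- paste0("X", seq_len(k))
  grid_mode <- is.null(newdata)
  if (grid_mode) {
    axes <- stats::setNames(rep(list(seq(-1, 1, length.out = grid_n)), k),
                            lin)
    if (!is.null(fix)) {
      bad <- setdiff(names(fix), lin)
      if (length(bad)) stop("unknown factor(s) in 'fix': ",
                            paste(bad, collapse = ", "), call. = FALSE)
      for (nm in names(fix)) axes[[nm]] <- as.numeric(fix[[nm]])
    }
    newdata <- do.call(expand.grid, axes)
  }
  nd <- as.data.frame(newdata)
  if (!all(lin %in% names(nd))) {
    if (ncol(nd) == k) names(nd) <- lin   # unnamed: assume X1..Xk order
    else stop("newdata must have columns ", paste(lin, collapse = ", "),
              call. = FALSE)
  }
  nd <- as.matrix(nd[, lin, drop = FALSE])
  if (any(abs(nd) > 1 + 1e-12))
    warning("prediction beyond the coded range [-1, 1] (extrapolation)")
  X <- cbind(1, nd, nd^2,
             do.call(cbind, lapply(utils::combn(k, 2, simplify = FALSE),
                                   function(p) nd[, p[1]] * nd[, p[2]])))
  pred <- drop(X %*% object$coefficients)
  if (grid_mode) cbind(as.data.frame(newdata), predicted = pred) else pred
}

#' @export
plot.quadfit <- function(x, factors = c(1L, 3L), fix_value = 0, grid_n = 41,
                         ...) {
  k <- sum(grepl("^X\\d+$", colnames(x$design)))
  lin <- paste0("X", seq_len(k))
  vary <- lin[factors]
  fix <- stats::setNames(rep(fix_value, k - 2L), setdiff(lin, vary))
  g <- predict(x, grid_n = grid_n, fix = fix)
  z <- matrix(g$predicted[order(g[[vary[2]]], g[[vary[1]]])],
              grid_n, grid_n)
  graphics::contour(seq(-1, 1, length.out = grid_n),
                    seq(-1, 1, length.out = grid_n), z,
                    xlab = paste(vary[1], "(coded)"),
                    ylab = paste(vary[2], "(coded)"),
                    main = paste("Fitted surface:", x$name), ...)
  invisible(g)
}

#' @export
simulate.quadfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$df_total + 1L
  mu <- object$fitted
  sig <- sqrt(object$sigma2)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(n, 0, sig)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- rownames(object$design)
  out
}

#' Fit one quadratic model per score
#'
#' @param scores Sample/observation x score matrix (e.g. from
#'   [compute_scores()]); rows must match the design's observation labels.
#' @param design Coded matrix or [factorial_design()].
#' @return Named list of `"quadfit"` objects, one per score column.
#' @export
fit_scores <- function(scores, design) {
  if (inherits(design, "factorial_design")) design <- coded_matrix(design)
  obs <- rownames(design)
  miss <- setdiff(obs, rownames(scores))
  if (length(miss))
    stop("score matrix lacks observation(s): ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  out <- lapply(colnames(scores), function(sc)
    fit_quadratic(scores[obs, sc], design, name = sc))
  stats::setNames(out, colnames(scores))
}
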