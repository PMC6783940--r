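#' Default marker panels
#'
#' Eleven marker genes grouped into the five panels used throughout:
#' pluripotency (OCT4, NANOG), ectoderm (FGF5, PAX6, P75), mesendoderm
#' (MIXL1, T), mesoderm (NKX2.5, MESP1) and endoderm (SOX17, PDX1).
#'
#' @return Named list: panel name to character vector of gene symbols.
#' @export
default_panels <- function() {
  list(
    Pluripotency = c("OCT4", "NANOG"),
    Ectoderm     = c("FGF5", "PAX6", "P75"),
    Mesendoderm  = c("MIXL1", "T"),
    Mesoderm     = c("NKX2.5", "MESP1"),
    Endoderm     = c("SOX17", "PDX1")
  )
}

#' Default lineage score weights
#'
#' The empirically fixed 5x5 weight matrix combining the five panel values
#' into pluripotency and lineage scores. Every row sums to zero, so a sample
#' with identical values on all panels scores zero on every axis.
#'
#' @return 5x5 numeric matrix, score x panel.
#' @export
default_weights <- function() {
  panels <- c("Pluripotency", "Ectoderm", "Mesendoderm", "Mesoderm",
              "Endoderm")
  w <- rbind(
    Pluripotency = c( 1.50, -0.25, -0.25, -0.50, -0.50),
    Ectoderm     = c(-0.25,  1.75, -0.50, -0.50, -0.50),
    Mesendoderm  = c(-1.00, -0.50,  1.00,  0.25,  0.25),
    Endoderm     = c(-1.00, -1.00,  0.50, -0.50,  2.00),
    Mesoderm     = c(-1.00, -1.00,  0.50,  2.00, -0.50)
  )
  colnames(w) <- panels
  w
}

# gene symbol aliases (case-insensitive matching is applied on top)
.gene_aliases <- c(BRACHYURY = "T", TBXT = "T", NGFR = "P75")

canonical_gene <- function(g) {
  up <- toupper(g)
  hit <- match(up, names(.gene_aliases))
  up[!is.na(hit)] <- .gene_aliases[hit[!is.na(hit)]]
  up
}

#' Min-max normalize expression per gene
#'
#' Rescales each gene column to `[0, 1]` using the minimum and maximum value
#' observed for that gene across the samples, so the least-expressing sample
#' maps to 0 and the highest to 1.
#'
#' @param expr Sample x gene numeric matrix (e.g. from
#'   [relative_expression()]).
#' @param cohort Optional character vector of sample labels over which the
#'   per-gene extremes are taken (default: all rows). Rows outside the
#'   cohort are still rescaled with the cohort's extremes.
#' @param degenerate `"error"` (default) fails if a gene is constant across
#'   the cohort; `"zero"` maps such a gene to 0 with a warning.
#' @return Numeric matrix of the same shape, values of cohort rows in
#'   `[0, 1]`.
#' @examples
#' m <- cbind(G = c(2, 4, 6))
#' rownames(m) <- c("a", "b", "c")
#' minmax_normalize(m)[, 1]  # 0, 0.5, 1
#' @export
minmax_normalize <- function(expr, cohort = NULL,
                             degenerate = c("error", "zero")) {
  degenerate <- match.arg(degenerate)
  m <- unclass(expr)
  if (nrow(m) < 2L) stop("need at least 2 samples to normalize",
                         call. = FALSE)
  if (!all(is.finite(m))) stop("expression values must be finite",
                               call. = FALSE)
  sub <- if (is.null(cohort)) m else {
    miss <- setdiff(cohort, rownames(m))
    if (length(miss))
      stop("cohort sample(s) not in matrix: ", paste(miss, collapse = ", "),
           call. = FALSE)
    m[cohort, , drop = FALSE]
  }
  lo <- apply(sub, 2, min)
  hi <- apply(sub, 2, max)
  rng <- hi - lo
  flat <- rng == 0
  if (any(flat)) {
    if (degenerate == "error")
      stop("gene(s) constant across the normalization cohort: ",
           paste(colnames(m)[flat], collapse = ", "), call. = FALSE)
    warning("constant gene(s) mapped to 0: ",
            paste(colnames(m)[flat], collapse = ", "))
    rng[flat] <- 1
    lo[flat] <- sub[1L, flat]  # center so result is 0
  }
  out <- sweep(sweep(m, 2, lo, "-"), 2, rng, "/")
  out
}

#' Average normalized genes into lineage panels
#'
#' @param norm Sample x gene matrix of normalized values (from
#'   [minmax_normalize()]).
#' @param panels Named list mapping panel names to gene symbols (default
#'   [default_panels()]). Gene matching is case-insensitive and understands
#'   the aliases T = Brachyury = TBXT and P75 = NGFR.
#' @return Sample x panel numeric matrix (values in `[0, 1]` when `norm`
#'   is).
#' @export
compute_panels <- function(norm, panels = default_panels()) {
  if (any(!nzchar(names(panels))) || any(lengths(panels) == 0L))
    stop("panels must be named and non-empty", call. = FALSE)
  have <- canonical_gene(colnames(norm))
  out <- matrix(NA_real_, nrow(norm), length(panels),
                dimnames = list(rownames(norm), names(panels)))
  for (p in names(panels)) {
    idx <- match(canonical_gene(panels[[p]]), have)
    if (anyNA(idx))
      stop("gene '", panels[[p]][which(is.na(idx))[1L]],
           "' of panel '", p, "' missing from expression data",
           call. = FALSE)
    out[, p] <- rowMeans(norm[, idx, drop = FALSE])
  }
  out
}

#' Weighted lineage and pluripotency scores
#'
#' Computes, for each sample, the five scores as fixed weighted sums of the
#' panel values: `score(s, k) = sum_p weights[k, p] * panel[s, p]`.
#'
#' @param panels Sample x panel matrix from [compute_panels()].
#' @param weights Score x panel weight matrix (default [default_weights()]);
#'   its column names must match the panel matrix columns.
#' @return Sample x score numeric matrix with attribute `"lineage"`: the
#'   per-sample argmax score name (a reporting convenience).
#' @examples
#' p <- matrix(c(1, 0, 0, 0, 0), 1,
#'             dimnames = list("s", names(default_panels())))
#' compute_scores(p)[, "Pluripotency"]  # 1.5
#' @export
compute_scores <- function(panels, weights = default_weights()) {
  if (!setequal(colnames(panels), colnames(weights)))
    stop("panel names of the data (", paste(colnames(panels), collapse = ", "),
         ") do not match the weight matrix columns", call. = FALSE)
  w <- weights[, colnames(panels), drop = FALSE]
  sc <- panels %*% t(w)
  attr(sc, "lineage") <- rownames(w)[max.col(sc, ties.method = "first")]
  sc
}

#' Run expression through normalization, panels and scores
#'
#' Convenience wrapper: [minmax_normalize()] then [compute_panels()] then
#' [compute_scores()].
#'
#' @inheritParams minmax_normalize
#' @inheritParams compute_panels
#' @inheritParams compute_scores
#' @return List with `normalized`, `panels` and `scores` matrices.
#' @export
score_expression <- function(expr, panels = default_panels(),
                             weights = default_weights(), cohort = NULL,
                             degenerate = "error") {
  norm <- minmax_normalize(expr, cohort = cohort, degenerate = degenerate)
  pan <- compute_panels(norm, panels)
  list(normalized = norm, panels = pan, scores = compute_scores(pan, weights))
}

#' Read panels or weights from YAML
#'
#' `read_panels_yaml` expects `panels: {name: [genes...]}`;
#' `read_weights_yaml` expects `weights: {score: {panel: value}}`.
#'
#' @param path YAML file path.
#' @return A panels list, or a score x panel weight matrix.
#' @export
read_panels_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$panels)) stop("YAML must contain 'panels'", call. = FALSE)
  lapply(spec$panels, function(g) as.character(unlist(g)))
}

#' @rdname read_panels_yaml
#' @export
read_weights_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$weights)) stop("YAML must contain 'weights'",
                                  call. = FALSE)
  rows <- names(spec$weights)
  cols <- names(spec$weights[[1L]])
  w <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (r in rows) w[r, ] <- unlist(spec$weights[[r]])[cols]
  w
}
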