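#' Define an experimental factor
#'
#' A factor is a soluble signaling input (growth factor or small molecule)
#' applied at three increasing concentration levels, the first of which must
#' be zero (no activation).
#'
#' @param name Short identifier, e.g. `"FGF2"`.
#' @param unit Concentration unit, e.g. `"ng/mL"` or `"uM"`. Must be
#'   non-empty.
#' @param levels Numeric vector of concentrations, strictly increasing, with
#'   exactly one zero as the first element.
#'
#' @return An object of class `"sf_factor"`.
#' @examples
#' define_factor("CHIR", "uM", c(0, 2, 6))
#' @export
define_factor <- function(name, unit, levels) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("factor 'name' must be a non-empty string", call. = FALSE)
  if (!is.character(unit) || length(unit) != 1L || !nzchar(unit))
    stop("factor 'unit' must be a non-empty string (e.g. \"ng/mL\")",
         call. = FALSE)
  levels <- as.numeric(levels)
  if (length(levels) < 2L)
    stop("factor '", name, "' needs at least 2 levels", call. = FALSE)
  if (any(levels < 0))
    stop("factor '", name, "' has negative concentration levels",
         call. = FALSE)
  if (any(diff(levels) <= 0))
    stop("levels of factor '", name, "' must be strictly increasing",
         call. = FALSE)
  if (sum(levels == 0) != 1L || levels[1L] != 0)
    stop("factor '", name,
         "' must have exactly one zero level, as the first level",
         call. = FALSE)
  structure(list(name = name, unit = unit, levels = levels),
            class = "sf_factor")
}

#' @export
print.sf_factor <- function(x, ...) {
  cat(sprintf("Factor %s [%s]: %s\n", x$name, x$unit,
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Build a multi-level full factorial design
#'
#' Crosses every level of every factor, in lexicographic order of level
#' indices with the *first* factor varying slowest and the *last* factor
#' varying fastest. Sample labels `"Sample 1"`, `"Sample 2"`, ... are
#' assigned in that order, so for the canonical FGF2/TGFb/CHIR design the
#' run table reproduces the published condition table row for row.
#'
#' @param factors A list of [define_factor()] objects with unique names.
#' @param replicates Optional named integer vector mapping sample labels to
#'   replicate counts (default 1 for every run). Replicates are biological:
#'   each extra replicate adds an observation row when the design is
#'   expanded with [coded_matrix()].
#' @param block_size Optional integer; partitions the runs, in order, into
#'   blocks of this size. Must divide the run count exactly.
#'
#' @return An object of class `"factorial_design"`: a list with elements
#'   `factors`, `runs` (a data.frame with `sample` plus one concentration
#'   column per factor, and a `block` column when blocked) and
#'   `replicates` (full named vector over all sample labels).
#' @seealso [canonical_design()] for the built-in 3^3 Wnt/FGF/TGFb design.
#' @examples
#' d <- factorial_design(list(
#'   define_factor("FGF2", "ng/mL", c(0, 35, 100)),
#'   define_factor("TGFb", "ng/mL", c(0, 0.7, 2)),
#'   define_factor("CHIR", "uM",    c(0, 2, 6))
#' ), block_size = 9)
#' nrow(d$runs)  # 27
#' @export
factorial_design <- function(factors, replicates = NULL, block_size = NULL) {
  if (!is.list(factors) || length(factors) < 1L)
    stop("'factors' must be a non-empty list of define_factor() objects",
         call. = FALSE)
  ok <- vapply(factors, inherits, logical(1), "sf_factor")
  if (!all(ok))
    stop("all elements of 'factors' must be created by define_factor()",
         call. = FALSE)
  fnames <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(fnames))
    stop("duplicate factor names: ",
         paste(unique(fnames[duplicated(fnames)]), collapse = ", "),
         call. = FALSE)

  n_levels <- vapply(factors, function(f) length(f$levels), integer(1))
  n_runs <- prod(n_levels)

  # level-index grid: first factor slowest-varying, last fastest
  idx <- vector("list", length(factors))
  rep_each <- rev(cumprod(c(1, rev(n_levels)[-length(n_levels)])))
  for (i in seq_along(factors)) {
    idx[[i]] <- rep(rep(seq_len(n_levels[i]), each = rep_each[i]),
                    length.out = n_runs)
  }
  runs <- data.frame(sample = paste("Sample", seq_len(n_runs)),
                     stringsAsFactors = FALSE)
  for (i in seq_along(factors))
    runs[[fnames[i]]] <- factors[[i]]$levels[idx[[i]]]

  if (!is.null(block_size)) {
    block_size <- as.integer(block_size)
    if (block_size < 1L || n_runs %% block_size != 0L)
      stop("block_size (", block_size, ") must divide the run count (",
           n_runs, ")", call. = FALSE)
    runs$block <- rep(seq_len(n_runs %/% block_size), each = block_size)
  }

  reps <- stats::setNames(rep(1L, n_runs), runs$sample)
  if (!is.null(replicates)) {
    if (is.null(names(replicates)) || !all(names(replicates) %in% runs$sample))
      stop("'replicates' must be a named vector over design sample labels",
           call. = FALSE)
    if (any(replicates < 1) || any(replicates != round(replicates)))
      stop("replicate counts must be positive integers", call. = FALSE)
    reps[names(replicates)] <- as.integer(replicates)
  }

  structure(list(factors = factors, runs = runs, replicates = reps),
            class = "factorial_design")
}

#' @export
print.factorial_design <- function(x, ...) {
  nl <- vapply(x$factors, function(f) length(f$levels), integer(1))
  cat(sprintf("Full factorial design: %s = %d runs, %d observations\n",
              paste(nl, collapse = " x "), nrow(x$runs), sum(x$replicates)))
  for (f in x$factors) print(f)
  if (!is.null(x$runs$block))
    cat(sprintf("Blocks: %d of size %d\n", max(x$runs$block),
                sum(x$runs$block == 1L)))
  invisible(x)
}

#' The canonical 3^3 Wnt/FGF/TGFb factorial design
#'
#' FGF2 at 0/35/100 ng/mL, TGFb at 0/0.7/2 ng/mL and CHIR99021 (Wnt
#' activation) at 0/2/6 uM: 27 culture conditions in three blocks of 9,
#' with Sample 1 (the unsupplemented E6 basal-medium condition) run in
#' triplicate.
#'
#' @param e6_triplicate Logical; replicate Sample 1 three times (default
#'   `TRUE`), giving 29 observations and 28 total degrees of freedom.
#' @return A [factorial_design()] object.
#' @export
canonical_design <- function(e6_triplicate = TRUE) {
  reps <- if (e6_triplicate) c("Sample 1" = 3L) else NULL
  factorial_design(
    list(define_factor("FGF2", "ng/mL", c(0, 35, 100)),
         define_factor("TGFb", "ng/mL", c(0, 0.7, 2)),
         define_factor("CHIR", "uM",    c(0, 2, 6))),
    replicates = reps, block_size = 9
  )
}

# expand the run table to one row per observation, honoring replicates;
# replicate observations get suffixed labels "Sample 1", "Sample 1_r2", ...
expand_observations <- function(design) {
  runs <- design$runs
  reps <- design$replicates[runs$sample]
  i <- rep(seq_len(nrow(runs)), reps)
  obs <- runs[i, , drop = FALSE]
  r <- sequence(reps)
  obs$observation <- ifelse(r == 1L, obs$sample,
                            paste0(obs$sample, "_r", r))
  rownames(obs) <- NULL
  obs
}

#' Coded quadratic design matrix
#'
#' Maps each concentration to a coded level and expands the design into the
#' 10-column model matrix of the full quadratic response surface: intercept,
#' three linear terms, three pure quadratic terms and three two-way
#' interactions. Under the default `"nominal"` coding each factor's three
#' levels are treated as nominal fractions 0, 1/3 and 1 of maximal
#' activation (by level index, regardless of the actual concentration
#' ratios) and centered/scaled as `X = 2*(f - 1/2)`, giving coded values
#' -1, -1/3 and +1. `"concentration"` coding instead uses the true
#' concentration fraction `conc/max(conc)` before the same centering.
#'
#' @param design A [factorial_design()] object.
#' @param coding `"nominal"` (default) or `"concentration"`.
#' @return A numeric matrix with one row per observation (replicates
#'   expanded) and columns `b0, X1, X2, X3, X1.2, X2.2, X3.2, X1.X2,
#'   X1.X3, X2.X3` (for three factors; names generalize). Row names are
#'   observation labels. Attributes: `observations` (data.frame from the
#'   expanded design) and `coding`.
#' @examples
#' cm <- coded_matrix(canonical_design())
#' dim(cm)           # 29 x 10
#' range(cm[, "X1"]) # -1, 1
#' @export
coded_matrix <- function(design, coding = c("nominal", "concentration")) {
  stopifnot(inherits(design, "factorial_design"))
  coding <- match.arg(coding)
  obs <- expand_observations(design)
  fnames <- vapply(design$factors, `[[`, character(1), "name")
  k <- length(fnames)

  X <- matrix(NA_real_, nrow(obs), k, dimnames = list(NULL, fnames))
  for (i in seq_len(k)) {
    f <- design$factors[[i]]
    conc <- obs[[f$name]]
    m <- match(conc, f$levels)
    if (anyNA(m))
      stop("concentration ", conc[which(is.na(m))[1L]], " of factor '",
           f$name, "' does not match a declared level", call. = FALSE)
    if (coding == "nominal" && length(f$levels) == 3L) {
      # nominal fractions {0, 1/3, 1} by level index, centered/scaled
      X[, i] <- c(-1, -1 / 3, 1)[m]
    } else {
      frac <- if (coding == "nominal") {
        (m - 1) / (length(f$levels) - 1)   # equally spaced by index
      } else {
        f$levels[m] / max(f$levels)
      }
      X[, i] <- 2 * (frac - 0.5)
    }
  }

  lin_names <- paste0("X", seq_len(k))
  quad <- X^2
  colnames(quad) <- paste0(lin_names, ".2")
  pairs <- utils::combn(k, 2)
  inter <- matrix(NA_real_, nrow(obs), ncol(pairs))
  colnames(inter) <- apply(pairs, 2, function(p)
    paste0(lin_names[p[1]], ".", lin_names[p[2]]))
  for (j in seq_len(ncol(pairs)))
    inter[, j] <- X[, pairs[1, j]] * X[, pairs[2, j]]

  out <- cbind(b0 = 1, X, quad, inter)
  colnames(out)[1 + seq_len(k)] <- lin_names
  rownames(out) <- obs$observation
  attr(out, "observations") <- obs
  attr(out, "coding") <- coding
  attr(out, "factor_names") <- fnames
  out
}

#' Write a design run table to TSV
#'
#' Exports one row per observation with sample label, concentrations and
#' coded columns.
#'
#' @param design A [factorial_design()].
#' @param path Output file path.
#' @param coding Passed to [coded_matrix()].
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path, coding = "nominal") {
  cm <- coded_matrix(design, coding = coding)
  obs <- attr(cm, "observations")
  tab <- cbind(obs, as.data.frame(cm[, -1, drop = FALSE]))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a design specification from YAML
#'
#' The YAML lists `factors` (each with `name`, `unit`, `levels`), optional
#' `replicates` (sample label to count) and optional `block_size`.
#'
#' @param path YAML file path.
#' @return A [factorial_design()] object.
#' @export
read_design_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$factors))
    stop("design YAML must contain a 'factors' list", call. = FALSE)
  factors <- lapply(spec$factors, function(f)
    define_factor(f$name, f$unit, unlist(f$levels)))
  reps <- if (!is.null(spec$replicates)) unlist(spec$replicates) else NULL
  factorial_design(factors, replicates = reps, block_size = spec$block_size)
}
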