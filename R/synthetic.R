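#' Synthetic qPCR scenario
#'
#' A scenario couples a factorial design with ground-truth per-gene quadratic
#' response surfaces on the calibrator-relative log2 expression scale, a
#' Gaussian Ct noise model and a seed, so that complete Ct tables can be
#' generated reproducibly and pipeline recovery measured against known
#' truth.
#'
#' Each target gene's true log2 relative expression at a factorial
#' observation is `L = x' beta` where `x` is the 10-term coded quadratic
#' expansion of the run's factor levels and `beta` the gene's coefficient
#' vector (order `b0, b1, b2, b3, b11, b22, b33, b12, b13, b23`). The
#' calibrator control (mTeSR1) has `L = 0` for every gene by construction —
#' surfaces are expressed relative to it — so in the noiseless limit the
#' 2^-ddCt pipeline returns exactly `2^L`. Observed cycle thresholds are
#' `Ct = baseline_ct - L + e` for targets and `Ct = reference_ct + e` for
#' the reference gene, with `e ~ N(0, noise_sd)` drawn independently per
#' replicate from a single seeded stream (genes in declared order, within
#' gene all observations, within observation the replicates).
#'
#' @param design A [factorial_design()].
#' @param surfaces Named list: gene symbol to numeric coefficient vector of
#'   length 10.
#' @param baseline_ct Named numeric: per-target-gene baseline Ct in cycles
#'   (must lie in (10, 35)); a single value is recycled.
#' @param reference_gene Reference gene symbol (default `"GAPDH"`); its
#'   surface is flat by construction (stable endogenous control).
#' @param reference_ct Reference gene Ct level in cycles (default 18).
#' @param noise_sd Gaussian Ct noise SD in cycles (default 0.25).
#' @param replicates Technical PCR replicates per (observation, gene)
#'   (default 3).
#' @param controls Named list of per-gene log2 override vectors for control
#'   samples (e.g. `E8`); the calibrator `mTeSR1` is always present with
#'   all-zero overrides.
#' @param control_replicates How many biological replicates of each control
#'   to generate (default 3).
#' @param seed Integer seed; fully determines the generated table.
#' @return Object of class `"sf_scenario"`.
#' @seealso [wnt_dominant_scenario()], [generate_ct()]
#' @export
synthetic_scenario <- function(design, surfaces, baseline_ct = 24,
                               reference_gene = "GAPDH", reference_ct = 18,
                               noise_sd = 0.25, replicates = 3,
                               controls = list(), control_replicates = 3,
                               seed = 1) {
  stopifnot(inherits(design, "factorial_design"))
  genes <- names(surfaces)
  if (is.null(genes) || any(!nzchar(genes)))
    stop("'surfaces' must be a named list of coefficient vectors",
         call. = FALSE)
  k <- length(design$factors)
  plen <- 1L + 2L * k + choose(k, 2L)
  for (g in genes) {
    surfaces[[g]] <- as.numeric(surfaces[[g]])
    if (length(surfaces[[g]]) != plen || !all(is.finite(surfaces[[g]])))
      stop("surface of gene '", g, "' must be ", plen, " finite coefficients",
           call. = FALSE)
  }
  if (length(baseline_ct) == 1L)
    baseline_ct <- stats::setNames(rep(baseline_ct, length(genes)), genes)
  if (!all(genes %in% names(baseline_ct)))
    stop("baseline_ct must cover every target gene", call. = FALSE)
  if (any(baseline_ct <= 10 | baseline_ct >= 35))
    stop("baseline Ct values must lie in (10, 35) cycles", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if ("mTeSR1" %in% names(controls))
    stop("mTeSR1 is the built-in calibrator control; its overrides are 0 ",
         "by construction", call. = FALSE)
  controls <- c(list(mTeSR1 = stats::setNames(rep(0, length(genes)), genes)),
                controls)
  for (cn in names(controls)) {
    if (!all(genes %in% names(controls[[cn]])))
      stop("control '", cn, "' override must cover every target gene",
           call. = FALSE)
  }
  structure(list(design = design, surfaces = surfaces,
                 baseline_ct = baseline_ct[genes],
                 reference_gene = reference_gene,
                 reference_ct = reference_ct, noise_sd = noise_sd,
                 replicates = as.integer(replicates),
                 controls = controls,
                 control_replicates = as.integer(control_replicates),
                 seed = as.integer(seed)),
            class = "sf_scenario")
}

#' @export
print.sf_scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic qPCR scenario: %d runs, %d genes + %s, noise SD %.3g cycles, %d replicate(s), seed %d\n",
    nrow(x$design$runs), length(x$surfaces), x$reference_gene,
    x$noise_sd, x$replicates, x$seed))
  cat("Controls:", paste(names(x$controls), collapse = ", "), "\n")
  invisible(x)
}

#' True log2 relative expression of a scenario
#'
#' Evaluates every gene's ground-truth surface at every observation
#' (factorial replicates expanded, controls appended).
#'
#' @param scenario An `"sf_scenario"`.
#' @param include_controls Append control observations (default `TRUE`).
#' @return Observation x gene numeric matrix of log2 relative expression.
#' @export
true_log2_expression <- function(scenario, include_controls = TRUE) {
  cm <- coded_matrix(scenario$design)
  genes <- names(scenario$surfaces)
  L <- sapply(genes, function(g) drop(cm %*% scenario$surfaces[[g]]))
  rownames(L) <- rownames(cm)
  if (include_controls) {
    for (cn in names(scenario$controls)) {
      ov <- scenario$controls[[cn]][genes]
      labs <- c(cn, if (scenario$control_replicates > 1L)
        paste0(cn, "_r", 2:scenario$control_replicates))
      L <- rbind(L, matrix(ov, length(labs), length(genes), byrow = TRUE,
                           dimnames = list(labs, genes)))
    }
  }
  L
}

#' Generate a synthetic Ct table
#'
#' Draws the full long-format Ct table for a scenario: every observation
#' (factorial conditions with replicates, plus controls) measured for every
#' target gene and the reference gene, with `replicates` technical PCR
#' replicates each, under seeded Gaussian Ct noise.
#'
#' @param scenario An `"sf_scenario"` from [synthetic_scenario()] or
#'   [wnt_dominant_scenario()].
#' @return A [ct_table()] with reference gene and calibrator (`mTeSR1`) set.
#' @examples
#' sc <- wnt_dominant_scenario(noise_sd = 0, seed = 7)
#' ct <- generate_ct(sc)
#' expr <- relative_expression(ct)
#' expr["mTeSR1", ]  # all 1: calibrator
#' @export
generate_ct <- function(scenario) {
  stopifnot(inherits(scenario, "sf_scenario"))
  set.seed(scenario$seed)
  L <- true_log2_expression(scenario, include_controls = TRUE)
  obs <- rownames(L)
  genes <- names(scenario$surfaces)
  r <- scenario$replicates

  blocks <- vector("list", length(genes) + 1L)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    mu <- rep(scenario$baseline_ct[[g]] - L[, g], each = r)
    eps <- stats::rnorm(length(mu), 0, scenario$noise_sd)
    blocks[[gi]] <- data.frame(
      sample = rep(obs, each = r), gene = g,
      replicate = rep(seq_len(r), times = length(obs)),
      ct = mu + eps, stringsAsFactors = FALSE)
  }
  mu <- rep(rep(scenario$reference_ct, length(obs)), each = r)
  eps <- stats::rnorm(length(mu), 0, scenario$noise_sd)
  blocks[[length(genes) + 1L]] <- data.frame(
    sample = rep(obs, each = r), gene = scenario$reference_gene,
    replicate = rep(seq_len(r), times = length(obs)),
    ct = mu + eps, stringsAsFactors = FALSE)

  ct_table(do.call(rbind, blocks), scenario$reference_gene, "mTeSR1")
}

#' Write a Ct table as long-format CSV
#'
#' Ct values are recorded with 4 decimals so files are byte-stable across
#' platforms.
#'
#' @param ct A [ct_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_csv <- function(ct, path) {
  rec <- ct$records
  rec$ct <- sprintf("%.4f", rec$ct)
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Wnt-dominant synthetic scenario
#'
#' A complete scenario over the canonical 27-condition design (Sample 1/E6
#' in triplicate, mTeSR1 and E8 controls) whose ground-truth surfaces encode
#' a dominant Wnt (CHIR) axis: mesendoderm and endoderm markers rise
#' steeply with CHIR, pluripotency and ectoderm markers fall, mesoderm
#' markers peak at the intermediate CHIR level (negative quadratic CHIR
#' term), FGF and TGFb contribute negatively to ectoderm markers, and an
#' FGF x CHIR synergy acts negatively on pluripotency markers and
#' positively on ectoderm/mesoderm markers. With the default effect scale
#' the lineage-score pipeline separates CHIR-free from CHIR-exposed
#' conditions and shows the interior mesoderm optimum.
#'
#' @param effect_scale Multiplies all non-intercept surface coefficients and
#'   control overrides (0 gives a null scenario with no factor structure).
#' @param noise_sd Gaussian Ct noise SD in cycles (default 0.25).
#' @param replicates Technical PCR replicates (default 3).
#' @param seed Integer seed.
#' @return An `"sf_scenario"`.
#' @export
wnt_dominant_scenario <- function(effect_scale = 1, noise_sd = 0.25,
                                  replicates = 3, seed = 1) {
  if (effect_scale < 0) stop("effect_scale must be >= 0", call. = FALSE)
  base <- wnt_dominant_surfaces()
  surfaces <- lapply(base$surfaces, function(b) {
    b[-1L] <- b[-1L] * effect_scale
    b
  })
  e8 <- base$e8_override * effect_scale
  synthetic_scenario(
    design = canonical_design(),
    surfaces = surfaces,
    baseline_ct = 24,
    noise_sd = noise_sd, replicates = replicates,
    controls = list(E8 = e8), seed = seed
  )
}

# ground-truth coefficients of the Wnt-dominant preset, log2 units on the
# coded scale; order b0, b1(FGF2), b2(TGFb), b3(CHIR), b11, b22, b33,
# b12, b13, b23
wnt_dominant_surfaces <- function() {
  surf <- function(b0 = 0, b1 = 0, b2 = 0, b3 = 0, b11 = 0, b22 = 0,
                   b33 = 0, b12 = 0, b13 = 0, b23 = 0)
    c(b0, b1, b2, b3, b11, b22, b33, b12, b13, b23)
  # CHIR responses are saturating: most of the effect is realized at the
  # intermediate level (2 uM already activates Wnt strongly), encoded by
  # concave/convex quadratic CHIR terms alongside dominant linear terms
  pluri <- surf(b0 = -3.5, b3 = -2.5, b33 = 1.25, b13 = -0.75)
  ecto  <- surf(b0 = -3.5, b1 = -0.7, b2 = -0.7, b3 = -2.0, b33 = 1.0,
                b13 = 0.6)
  mesend <- surf(b0 = 3.0, b3 = 2.0, b33 = -2.0)
  meso  <- surf(b0 = 2.0, b3 = -2.0, b33 = -3.0, b13 = 0.6)
  endo  <- surf(b0 = 2.5, b2 = 0.5, b3 = 2.0, b33 = -2.0)
  surfaces <- list(
    OCT4 = pluri, NANOG = pluri,
    FGF5 = ecto, PAX6 = ecto, P75 = ecto,
    MIXL1 = mesend, T = mesend,
    NKX2.5 = meso, MESP1 = meso,
    SOX17 = endo, PDX1 = endo
  )
  e8 <- c(OCT4 = 0, NANOG = 0, FGF5 = -0.5, PAX6 = -0.5, P75 = -0.5,
          MIXL1 = -0.5, T = -0.5, NKX2.5 = -3, MESP1 = -3,
          SOX17 = -0.5, PDX1 = -0.5)
  list(surfaces = surfaces, e8_override = e8)
}

#' Read a scenario specification from YAML
#'
#' The YAML carries `surfaces` (gene to 10 coefficients), optional
#' `baseline_ct`, `noise_sd`, `replicates`, `seed` and `controls` (control
#' label to per-gene log2 overrides). The design is the canonical
#' 27-condition factorial unless a `design` block (as in
#' [read_design_yaml()]) is present.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return An `"sf_scenario"`.
#' @export
read_scenario_yaml <- function(path, seed = NULL) {
  spec <- yaml::read_yaml(path)
  design <- if (!is.null(spec$design)) {
    factors <- lapply(spec$design$factors, function(f)
      define_factor(f$name, f$unit, unlist(f$levels)))
    reps <- if (!is.null(spec$design$replicates))
      unlist(spec$design$replicates) else NULL
    factorial_design(factors, replicates = reps,
                     block_size = spec$design$block_size)
  } else canonical_design()
  controls <- lapply(spec$controls, unlist)
  synthetic_scenario(
    design = design,
    surfaces = lapply(spec$surfaces, unlist),
    baseline_ct = if (!is.null(spec$baseline_ct))
      unlist(spec$baseline_ct) else 24,
    reference_gene = spec$reference_gene %||% "GAPDH",
    reference_ct = spec$reference_ct %||% 18,
    noise_sd = spec$noise_sd %||% 0.25,
    replicates = spec$replicates %||% 3,
    controls = controls %||% list(),
    seed = seed %||% spec$seed %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
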