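#' Assemble a pipeline configuration
#'
#' Collects all choices for a full analysis run: where the Ct data come from
#' (a file or a synthetic scenario), quantification settings, the scoring
#' configuration and the model/clustering options.
#'
#' @param ct Path to a long-format Ct CSV, a [ct_table()], or `NULL` when a
#'   `scenario` is supplied.
#' @param scenario An `"sf_scenario"` (or path to a scenario YAML) used to
#'   generate the Ct table when `ct` is `NULL`.
#' @param design A [factorial_design()] (default [canonical_design()]).
#' @param reference_gene,calibrator_sample Quantification settings (defaults
#'   `"GAPDH"`, `"mTeSR1"`).
#' @param panels,weights Scoring configuration (defaults [default_panels()],
#'   [default_weights()]).
#' @param normalize_cohort `"all"` (default): min-max extremes over every
#'   sample including controls; `"factorial"`: extremes over the factorial
#'   observations only. Control samples never enter the model fits (they
#'   have no factor levels), preserving the 28-df bookkeeping of the
#'   canonical design.
#' @param coding Level coding for the model matrix (see [coded_matrix()]).
#' @param k Number of clusters to cut (default 2).
#' @param pca_scale Unit-variance scaling in PCA (default `FALSE`).
#' @param out Optional output directory; when set, [run_pipeline()] writes
#'   every intermediate artifact there as TSV plus a JSON report.
#' @param seed Seed recorded in provenance and used for scenario generation
#'   when the scenario does not carry one.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(ct = NULL, scenario = NULL,
                            design = canonical_design(),
                            reference_gene = "GAPDH",
                            calibrator_sample = "mTeSR1",
                            panels = default_panels(),
                            weights = default_weights(),
                            normalize_cohort = c("all", "factorial"),
                            coding = "nominal",
                            k = 2, pca_scale = FALSE,
                            out = NULL, seed = NULL) {
  normalize_cohort <- match.arg(normalize_cohort)
  if (is.null(ct) && is.null(scenario))
    stop("provide either 'ct' (data) or 'scenario' (generator)",
         call. = FALSE)
  if (is.character(scenario)) scenario <- read_scenario_yaml(scenario,
                                                             seed = seed)
  if (!is.null(scenario) && !is.null(seed)) scenario$seed <- as.integer(seed)
  structure(list(ct = ct, scenario = scenario, design = design,
                 reference_gene = reference_gene,
                 calibrator_sample = calibrator_sample,
                 panels = panels, weights = weights,
                 normalize_cohort = normalize_cohort,
                 coding = coding, k = k, pca_scale = pca_scale,
                 out = out, seed = seed),
            class = "pipeline_config")
}

#' Validate pipeline inputs without running them
#'
#' Checks file existence and dialect, panel gene coverage and the
#' design/sample-label join; never mutates data. Findings are returned (and
#' printed) as human-readable messages; an empty character vector means the
#' configuration is runnable.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of findings (zero-length when clean),
#'   invisibly; also printed.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  findings <- character()
  note <- function(...) findings <<- c(findings, paste0(...))

  ct <- config$ct
  if (is.character(ct)) {
    if (!file.exists(ct)) {
      note("Ct file does not exist: ", ct)
      ct <- NULL
    } else {
      head1 <- utils::read.csv(ct, nrows = 1)
      need <- c("sample", "gene", "replicate", "ct")
      if (!all(need %in% names(head1)))
        note("Ct CSV must have header sample,gene,replicate,ct: ", ct)
      else ct <- tryCatch(
        read_ct_csv(ct, config$reference_gene, config$calibrator_sample),
        error = function(e) { note(conditionMessage(e)); NULL })
    }
  }
  if (inherits(ct, "ct_table")) {
    genes <- canonical_gene(unique(ct$records$gene))
    for (p in names(config$panels)) {
      miss <- setdiff(canonical_gene(config$panels[[p]]), genes)
      if (length(miss))
        note("panel '", p, "' gene(s) missing from Ct data: ",
             paste(miss, collapse = ", "))
    }
    labs <- unique(ct$records$sample)
    design_obs <- expand_observations(config$design)$observation
    known <- c(design_obs, config$calibrator_sample)
    extra <- setdiff(labs, c(known, unlist(lapply(
      c("mTeSR1", "E8"), function(cn) c(cn, paste0(cn, "_r", 2:9))))))
    if (length(extra))
      note("sample(s) in Ct table absent from design/controls: ",
           paste(utils::head(extra, 5), collapse = ", "))
    missing_obs <- setdiff(design_obs, labs)
    if (length(missing_obs))
      note("design observation(s) missing from Ct table: ",
           paste(utils::head(missing_obs, 5), collapse = ", "))
  }
  if (!setequal(names(config$panels), colnames(config$weights)))
    note("panel names do not match weight matrix columns")
  if (length(findings)) {
    cat("Validation findings:\n")
    for (f in findings) cat(" -", f, "\n")
  } else cat("Validation: no findings\n")
  invisible(findings)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: Ct acquisition (file or seeded synthetic generation),
#' 2^-ddCt relative expression, min-max normalization, panel aggregation and
#' lineage scoring, one full quadratic response-surface model per score with
#' per-term ANOVA, UPGMA clustering of the samples on their score vectors
#' (Pearson correlation distance) and PCA with SVD imputation. When
#' `config$out` is set, every intermediate artifact is written as TSV along
#' with a JSON run report.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `"run_report"` with elements `expression`,
#'   `normalized`, `panels`, `scores`, `fits` (per-score `"quadfit"`),
#'   `anova` (per-score ANOVA tables), `clustering` (`hclust`), `clusters`
#'   (k-cut assignment), `pca` (`"pca_svd"`) and `provenance`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(scenario = wnt_dominant_scenario(seed = 42))
#' rep <- run_pipeline(cfg)
#' rep$fits$Mesendoderm
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ct <- stage("ingest", {
    if (!is.null(config$ct)) {
      if (is.character(config$ct))
        read_ct_csv(config$ct, config$reference_gene,
                    config$calibrator_sample)
      else config$ct
    } else generate_ct(config$scenario)
  })

  expr <- stage("express", relative_expression(ct))

  design_obs <- expand_observations(config$design)$observation
  cohort <- if (config$normalize_cohort == "factorial")
    intersect(rownames(expr), design_obs) else NULL
  scored <- stage("score",
                  score_expression(expr, panels = config$panels,
                                   weights = config$weights,
                                   cohort = cohort))

  cm <- stage("design", coded_matrix(config$design, coding = config$coding))
  fit_rows <- intersect(rownames(scored$scores), rownames(cm))
  fits <- stage("fit", fit_scores(scored$scores, cm))
  anovas <- lapply(fits, anova)

  dmat <- stage("cluster", pearson_distance(scored$scores))
  dend <- upgma_cluster(dmat)
  clusters <- cut_clusters(dend, config$k)

  pca <- stage("pca", pca_svd(scored$scores, center = TRUE,
                              scale. = config$pca_scale))

  report <- structure(list(
    expression = expr, normalized = scored$normalized,
    panels = scored$panels, scores = scored$scores,
    fits = fits, anova = anovas,
    clustering = dend, clusters = clusters, pca = pca,
    provenance = list(
      seed = config$seed %||% config$scenario$seed,
      calibrator = config$calibrator_sample,
      reference_gene = config$reference_gene,
      normalize_cohort = config$normalize_cohort,
      coding = config$coding, k = config$k,
      n_fit_observations = length(fit_rows),
      timestamp_free = TRUE)
  ), class = "run_report")

  if (!is.null(config$out)) write_report(report, config$out)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf(" expression: %d samples x %d genes\n", nrow(x$expression),
              ncol(x$expression)))
  cat(sprintf(" models: %s\n", paste(names(x$fits), collapse = ", ")))
  for (nm in names(x$fits))
    cat(sprintf("  %-13s R2 = %.3f, R2-adj = %.3f\n", nm, x$fits[[nm]]$r2,
                x$fits[[nm]]$r2_adj))
  cat(sprintf(" clusters (k = %d): sizes %s\n",
              max(x$clusters), paste(table(x$clusters), collapse = ", ")))
  cat(sprintf(" PCA: PC1 %.1f%%, PC2 %.1f%%\n",
              100 * x$pca$explained[1], 100 * x$pca$explained[2]))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(m, f) {
    tab <- data.frame(sample = rownames(m), as.data.frame(unclass(m)),
                      check.names = FALSE)
    utils::write.table(tab, file.path(out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wtsv(report$expression, "expression.tsv")
  wtsv(report$normalized, "normalized.tsv")
  wtsv(report$panels, "panels.tsv")
  wtsv(report$scores, "scores.tsv")
  coefs <- do.call(rbind, lapply(names(report$fits), function(nm) {
    a <- report$anova[[nm]]
    data.frame(response = nm,
               term = c("b0", a$term),
               estimate = as.numeric(report$fits[[nm]]$coefficients),
               ss = c(NA, a$ss), f = c(NA, a$f), p = c(NA, a$p),
               significant = c(NA, a$significant))
  }))
  utils::write.table(coefs, file.path(out_dir, "model_terms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- lapply(report$fits, function(f)
    list(r2 = f$r2, r2_adj = f$r2_adj, df_total = f$df_total,
         df_model = f$df_model, df_residual = f$df_residual))
  clus <- as.list(report$clusters)
  jsonlite::write_json(
    list(models = summ, clusters = clus,
         pca_explained = as.numeric(report$pca$explained),
         provenance = report$provenance),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (requireNamespace("ape", quietly = TRUE))
    write_newick(report$clustering, file.path(out_dir, "dendrogram.nwk"))
  invisible(out_dir)
}
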