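#' Construct a Ct table
#'
#' Holds raw real-time PCR cycle-threshold values in long format together
#' with the endogenous control (reference) gene and the calibrator sample
#' used for relative quantification.
#'
#' @param records A data.frame with columns `sample`, `gene`, `replicate`
#'   and `ct` (cycles; finite, positive).
#' @param reference_gene Gene symbol of the endogenous control (e.g.
#'   `"GAPDH"`). Must be measured in every sample that has any target
#'   measurement.
#' @param calibrator_sample Sample label used as calibrator (e.g.
#'   `"mTeSR1"`); must carry the reference gene and every target gene.
#' @param na_action `"error"` (default) rejects undetermined/NA Ct entries;
#'   `"drop"` removes the affected replicate rows with a warning.
#'
#' @return An object of class `"ct_table"`.
#' @export
ct_table <- function(records, reference_gene, calibrator_sample,
                     na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  need <- c("sample", "gene", "replicate", "ct")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("'records' must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  records <- records[need]
  records$sample <- as.character(records$sample)
  records$gene <- as.character(records$gene)
  records$ct <- as.numeric(records$ct)

  bad <- !is.finite(records$ct)
  if (any(bad)) {
    if (na_action == "error")
      stop("non-finite Ct values found (first offending sample: ",
           records$sample[which(bad)[1L]],
           "); use na_action = \"drop\" to discard them", call. = FALSE)
    warning(sum(bad), " replicate record(s) with undetermined Ct dropped")
    records <- records[!bad, , drop = FALSE]
  }
  if (any(records$ct <= 0))
    stop("Ct values must be > 0 cycles", call. = FALSE)

  samples <- unique(records$sample)
  has_ref <- samples %in% records$sample[records$gene == reference_gene]
  if (!all(has_ref))
    stop("reference gene '", reference_gene, "' missing for sample(s): ",
         paste(samples[!has_ref], collapse = ", "), call. = FALSE)
  if (!calibrator_sample %in% samples)
    stop("calibrator sample '", calibrator_sample,
         "' absent from the Ct table", call. = FALSE)
  targets <- setdiff(unique(records$gene), reference_gene)
  cal_genes <- unique(records$gene[records$sample == calibrator_sample])
  missing_cal <- setdiff(targets, cal_genes)
  if (length(missing_cal))
    stop("calibrator sample '", calibrator_sample,
         "' lacks measurement for gene(s): ",
         paste(missing_cal, collapse = ", "), call. = FALSE)

  structure(list(records = records, reference_gene = reference_gene,
                 calibrator_sample = calibrator_sample),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf(
    "Ct table: %d records, %d samples, %d genes (reference %s, calibrator %s)\n",
    nrow(x$records), length(unique(x$records$sample)),
    length(unique(x$records$gene)), x$reference_gene, x$calibrator_sample))
  invisible(x)
}

#' Read a long-format Ct CSV
#'
#' Expects a header `sample,gene,replicate,ct`.
#'
#' @inheritParams ct_table
#' @param path CSV file path.
#' @return A [ct_table()] object.
#' @export
read_ct_csv <- function(path, reference_gene, calibrator_sample,
                        na_action = "error") {
  ct_table(utils::read.csv(path, stringsAsFactors = FALSE),
           reference_gene, calibrator_sample, na_action = na_action)
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged on the Ct scale; within each sample the
#' target gene is normalized to the endogenous control
#' (`dCt = mean Ct_target - mean Ct_reference`), then to the calibrator
#' sample (`ddCt = dCt_sample - dCt_calibrator`), and the relative quantity
#' is `2^-ddCt`. The calibrator sample therefore maps to exactly 1 for every
#' gene.
#'
#' @param ct A [ct_table()] object.
#' @return A numeric sample x gene matrix of class `"expression_matrix"`
#'   (strictly positive; calibrator row identically 1), with attributes
#'   `method`, `reference_gene` and `calibrator_sample`.
#' @examples
#' rec <- data.frame(
#'   sample = rep(c("A", "Cal"), each = 2),
#'   gene = rep(c("T", "GAPDH"), 2),
#'   replicate = 1,
#'   ct = c(25, 20, 24, 20))
#' relative_expression(ct_table(rec, "GAPDH", "Cal"))  # A,T = 0.5
#' @export
relative_expression <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  rec <- ct$records
  # replicate-mean Ct per (sample, gene)
  key <- interaction(rec$sample, rec$gene, drop = TRUE, sep = "\r")
  mean_ct <- c(tapply(rec$ct, key, mean))
  parts <- strsplit(names(mean_ct), "\r", fixed = TRUE)
  ms <- vapply(parts, `[[`, character(1), 1L)
  mg <- vapply(parts, `[[`, character(1), 2L)

  samples <- unique(rec$sample)
  genes <- setdiff(unique(rec$gene), ct$reference_gene)

  ref_ct <- stats::setNames(
    mean_ct[mg == ct$reference_gene][match(
      samples, ms[mg == ct$reference_gene])], samples)

  wide <- matrix(NA_real_, length(samples), length(genes),
                 dimnames = list(samples, genes))
  tgt <- mg != ct$reference_gene
  wide[cbind(match(ms[tgt], samples), match(mg[tgt], genes))] <- mean_ct[tgt]

  dct <- wide - ref_ct[samples]           # recycles by column
  ddct <- sweep(dct, 2, dct[ct$calibrator_sample, ], "-")
  expr <- 2^(-ddct)
  if (anyNA(expr)) {
    miss <- which(is.na(expr), arr.ind = TRUE)
    stop("missing (sample, gene) measurement(s), e.g. sample '",
         rownames(expr)[miss[1, 1]], "', gene '",
         colnames(expr)[miss[1, 2]], "'", call. = FALSE)
  }
  structure(expr, class = c("expression_matrix", "matrix", "array"),
            method = "2^-ddCt", reference_gene = ct$reference_gene,
            calibrator_sample = ct$calibrator_sample)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Relative expression (%s, calibrator %s): %d samples x %d genes\n",
              attr(x, "method"), attr(x, "calibrator_sample"),
              nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE], digits = 4)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Write an expression matrix as wide TSV
#'
#' @param expr An `"expression_matrix"` (or any sample x gene matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  tab <- data.frame(sample = rownames(expr), unclass(expr),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
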