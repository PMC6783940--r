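# Shared helpers: tiny data builders and independent oracles.

# long-format Ct records from a named list: genes x samples matrix of mean
# Ct, optionally with explicit replicate vectors
make_ct_records <- function(ct_by_sample_gene) {
  do.call(rbind, lapply(names(ct_by_sample_gene), function(s) {
    genes <- ct_by_sample_gene[[s]]
    do.call(rbind, lapply(names(genes), function(g) {
      v <- genes[[g]]
      data.frame(sample = s, gene = g, replicate = seq_along(v), ct = v,
                 stringsAsFactors = FALSE)
    }))
  }))
}

# Brute-force UPGMA: at every step recompute every cluster-pair distance as
# the mean of all cross-pair distances taken from the ORIGINAL matrix.
# Returns the sorted sequence of merge heights.
upgma_oracle_heights <- function(dmat) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      h <- mean(dmat[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights[step] <- best[1]
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# run table of the canonical factorial design joined to score rows
factorial_run_info <- function(score_matrix,
                               design = canonical_design()) {
  obs <- stemfactor:::expand_observations(design)
  obs[obs$observation %in% rownames(score_matrix), ]
}

rand_index <- stemfactor:::rand_index
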