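# Independent brute-force oracles: deliberately naive per-cell / per-gene
# loops, kept free of any package internals so they can contradict the
# implementation.

oracle_cpm <- function(counts) {
  out <- counts * 0
  for (s in seq_len(ncol(counts))) {
    lib <- sum(counts[, s])
    for (g in seq_len(nrow(counts))) {
      out[g, s] <- counts[g, s] / lib * 1e6
    }
  }
  out
}

oracle_filter_keep <- function(counts, meta, cpm_threshold = 1,
                               prevalence_fraction = 0.2,
                               min_prevalent_samples = 2) {
  cpm <- oracle_cpm(counts)
  need <- max(ceiling(prevalence_fraction * ncol(counts)),
              min_prevalent_samples)
  stages <- unique(as.character(meta$stage))
  keep <- logical(nrow(counts))
  for (g in seq_len(nrow(counts))) {
    a <- sum(cpm[g, ] >= cpm_threshold) >= need
    b <- TRUE
    for (st in stages) {
      cols <- which(as.character(meta$stage) == st)
      if (!any(counts[g, cols] > 0)) b <- FALSE
    }
    keep[g] <- a && b
  }
  rownames(counts)[keep]
}

oracle_wcss <- function(profiles, cluster, centers) {
  tot <- 0
  for (g in seq_len(nrow(profiles))) {
    tot <- tot + sum((profiles[g, ] - centers[cluster[g], ])^2)
  }
  tot
}

oracle_nearest <- function(profiles, centers) {
  out <- integer(nrow(profiles))
  for (g in seq_len(nrow(profiles))) {
    d <- apply(centers, 1L, function(ct) sum((profiles[g, ] - ct)^2))
    out[g] <- which.min(d)
  }
  out
}

oracle_transition_counts <- function(ref, cmp, k) {
  shared <- intersect(names(ref), names(cmp))
  m <- matrix(0L, k, k)
  for (g in shared) m[ref[[g]], cmp[[g]]] <- m[ref[[g]], cmp[[g]]] + 1L
  m
}

oracle_region_count <- function(sets, genes) {
  # for each gene, its exact membership pattern
  pat <- vapply(genes, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1L))],
          collapse = "&")
  }, character(1L))
  table(pat)
}

oracle_ddct <- function(ct, nuclear, reference) {
  # spreadsheet-style: average replicates, then dCt, ddCt, 2^-ddCt
  key <- paste(ct$sample_id, ct$target)
  mean_ct <- tapply(ct$ct, key, mean)
  samples <- unique(ct[, c("sample_id", "group")])
  targets <- setdiff(unique(ct$target), nuclear)
  out <- list()
  for (tg in targets) {
    dct <- sapply(samples$sample_id, function(s) {
      mean_ct[[paste(s, tg)]] - mean_ct[[paste(s, nuclear)]]
    })
    ref_mean <- mean(dct[samples$group == reference])
    out[[tg]] <- 2^(-(dct - ref_mean))
  }
  out
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
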