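# Closed-form assay summaries: delta-delta-Ct relative quantification of
# mtDNA copy number, and targeted bisulfite percent methylation.

#' Relative mtDNA/nDNA ratio by the delta-delta-Ct method
#'
#' For each sample and mitochondrial target, replicate Ct values are
#' averaged, dCt = Ct_mt - Ct_nuclear is formed, centered on the
#' arithmetic mean dCt of the reference group (equivalently the geometric
#' mean of ratios, so the reference group's geometric-mean ratio is 1 by
#' construction), and the relative copy-number ratio 2^(-ddCt) is
#' reported. When several mitochondrial targets are assayed (e.g. ND1 and
#' Cox3 against 18S) each is normalized separately and their per-sample
#' mean is reported as target `"mean_mt"`.
#'
#' @param ct Data frame with columns `sample_id`, `target`, `ct`, `group`
#'   and optionally `replicate`. Ct values must lie in (0, 45).
#' @param nuclear_target Label of the nuclear normalizer. Default "18S".
#' @param reference_group Label of the reference group; defaults to the
#'   first group in file order.
#' @return List with `ratios`, a data frame `sample_id`, `group`,
#'   `target`, `delta_ct`, `ddct`, `ratio`; and `group_stats`, Welch
#'   two-sample t-test p-values comparing each non-reference group to the
#'   reference per target (NA when a group has fewer than 2 samples).
#' @export
ddct_ratio <- function(ct, nuclear_target = "18S", reference_group = NULL) {
  need <- c("sample_id", "target", "ct", "group")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0L)
    stop_traj("Ct table is missing column(s): %s", paste(miss, collapse = ", "))
  if (any(!is.finite(ct$ct) | ct$ct <= 0 | ct$ct >= 45))
    stop_traj("Ct values must be finite and lie in (0, 45)")
  if (!nuclear_target %in% ct$target)
    stop_traj("nuclear target '%s' absent from the Ct table", nuclear_target)
  if (is.null(reference_group)) reference_group <- as.character(ct$group[1L])
  if (!reference_group %in% ct$group)
    stop_traj("reference group '%s' has no samples", reference_group)

  # replicate-averaged Ct per (sample, target)
  mean_ct <- stats::aggregate(ct ~ sample_id + target + group, data = ct,
                              FUN = mean)
  samples <- unique(mean_ct[, c("sample_id", "group")])
  nuc <- mean_ct[mean_ct$target == nuclear_target, , drop = FALSE]
  missing_nuc <- setdiff(samples$sample_id, nuc$sample_id)
  if (length(missing_nuc) > 0L)
    stop_traj("sample(s) without a nuclear ('%s') Ct: %s", nuclear_target,
              paste(missing_nuc, collapse = ", "))
  mt_targets <- setdiff(unique(mean_ct$target), nuclear_target)
  if (length(mt_targets) == 0L)
    stop_traj("no mitochondrial target in the Ct table")

  rows <- lapply(mt_targets, function(tg) {
    mt <- mean_ct[mean_ct$target == tg, , drop = FALSE]
    m <- merge(mt, nuc[, c("sample_id", "ct")], by = "sample_id",
               suffixes = c("_mt", "_nuc"))
    dct <- m$ct_mt - m$ct_nuc
    ref_mean <- mean(dct[m$group == reference_group])
    ddct <- dct - ref_mean
    data.frame(sample_id = m$sample_id, group = m$group, target = tg,
               delta_ct = dct, ddct = ddct, ratio = 2^(-ddct),
               stringsAsFactors = FALSE)
  })
  ratios <- do.call(rbind, rows)
  # per-sample mean over mitochondrial targets
  if (length(mt_targets) > 1L) {
    agg <- stats::aggregate(cbind(delta_ct, ddct, ratio) ~ sample_id + group,
                            data = ratios, FUN = mean)
    agg$target <- "mean_mt"
    ratios <- rbind(ratios, agg[, names(ratios)])
  }
  ratios <- ratios[order(ratios$target, ratios$sample_id), , drop = FALSE]
  rownames(ratios) <- NULL

  other_groups <- setdiff(unique(as.character(ratios$group)), reference_group)
  stats_rows <- list()
  for (tg in unique(ratios$target)) for (g in other_groups) {
    a <- ratios$ratio[ratios$target == tg & ratios$group == reference_group]
    b <- ratios$ratio[ratios$target == tg & ratios$group == g]
    p <- if (length(a) >= 2L && length(b) >= 2L)
      tryCatch(stats::t.test(b, a)$p.value, error = function(e) NA_real_)
    else NA_real_
    stats_rows[[length(stats_rows) + 1L]] <- data.frame(
      target = tg, group = g, reference = reference_group,
      mean_ratio = mean(b), p_value = p, stringsAsFactors = FALSE)
  }
  group_stats <- if (length(stats_rows) > 0L) do.call(rbind, stats_rows)
                 else data.frame()
  list(ratios = ratios, group_stats = group_stats,
       reference_group = reference_group)
}

#' Percent methylation from targeted bisulfite counts
#'
#' Per CpG and sample: percent = methylated / (methylated + unmethylated)
#' x 100, reported only where coverage reaches `min_coverage` and flagged
#' missing otherwise. Per amplicon and sample: the coverage-weighted mean
#' over its passing CpGs (an amplicon whose CpGs all fail coverage is
#' reported missing, never zero). Group means are unweighted means over
#' samples.
#'
#' @param mc Data frame with columns `amplicon`, `cpg_index`,
#'   `methylated`, `unmethylated`, `sample_id`, `group`.
#' @param min_coverage Minimum reads (methylated + unmethylated) for a CpG
#'   to contribute. Default 10.
#' @return List with `per_cpg` (adds `coverage`, `percent`, `flagged`),
#'   `per_amplicon` (`amplicon`, `sample_id`, `group`, `percent`,
#'   `n_cpgs_passing`, `missing`), and `group_means` (`amplicon`, `group`,
#'   `mean_percent`, `n_samples`).
#' @export
methylation_summary <- function(mc, min_coverage = 10L) {
  need <- c("amplicon", "cpg_index", "methylated", "unmethylated",
            "sample_id", "group")
  miss <- setdiff(need, names(mc))
  if (length(miss) > 0L)
    stop_traj("methylation table is missing column(s): %s",
              paste(miss, collapse = ", "))
  if (any(mc$methylated < 0 | mc$unmethylated < 0))
    stop_traj("read counts must be non-negative")
  per_cpg <- mc
  per_cpg$coverage <- mc$methylated + mc$unmethylated
  per_cpg$percent <- ifelse(per_cpg$coverage >= min_coverage,
                            100 * mc$methylated / per_cpg$coverage,
                            NA_real_)
  per_cpg$flagged <- per_cpg$coverage < min_coverage

  key <- interaction(per_cpg$amplicon, per_cpg$sample_id, drop = TRUE)
  amp_rows <- lapply(split(per_cpg, key), function(d) {
    ok <- !d$flagged
    pct <- if (any(ok))
      sum(d$percent[ok] * d$coverage[ok]) / sum(d$coverage[ok])
    else NA_real_
    data.frame(amplicon = d$amplicon[1L], sample_id = d$sample_id[1L],
               group = d$group[1L], percent = pct,
               n_cpgs_passing = sum(ok), missing = !any(ok),
               stringsAsFactors = FALSE)
  })
  per_amplicon <- do.call(rbind, amp_rows)
  per_amplicon <- per_amplicon[order(per_amplicon$amplicon,
                                     per_amplicon$sample_id), , drop = FALSE]
  rownames(per_amplicon) <- NULL

  gm_key <- interaction(per_amplicon$amplicon, per_amplicon$group,
                        drop = TRUE)
  gm_rows <- lapply(split(per_amplicon, gm_key), function(d) {
    data.frame(amplicon = d$amplicon[1L], group = d$group[1L],
               mean_percent = mean(d$percent, na.rm = TRUE),
               n_samples = sum(!is.na(d$percent)),
               stringsAsFactors = FALSE)
  })
  group_means <- do.call(rbind, gm_rows)
  group_means <- group_means[order(group_means$amplicon,
                                   group_means$group), , drop = FALSE]
  rownames(group_means) <- NULL
  group_means$mean_percent[group_means$n_samples == 0L] <- NA_real_
  list(per_cpg = per_cpg, per_amplicon = per_amplicon,
       group_means = group_means)
}
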