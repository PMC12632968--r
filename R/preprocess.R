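# Expression filter, CPM transform, gene-wise Z-scores and stage-mean
# trajectory profiles.

#' Counts per million
#'
#' Scales each sample's counts by its total library size (summed over all
#' genes of the supplied matrix, i.e. before any filtering) times 1e6.
#' Library sizes must therefore be computed on the raw matrix and genes
#' filtered afterwards, so that the filter threshold refers to the
#' sample's true sequencing depth.
#'
#' @param counts Validated count matrix (genes x samples).
#' @return Numeric matrix of CPM values with the same dimnames.
#' @export
compute_cpm <- function(counts) {
  counts <- validate_counts(counts)
  libsize <- colSums(counts)
  zero <- colnames(counts)[libsize == 0]
  if (length(zero) > 0L)
    stop_traj("sample(s) with zero library size: %s",
              paste(zero, collapse = ", "))
  sweep(counts, 2L, libsize, "/") * 1e6
}

#' Prevalence and stage-detection expression filter
#'
#' A gene is retained iff
#' (a) its CPM reaches `cfg$cpm_threshold` in at least
#'     `max(ceiling(cfg$prevalence_fraction * n_samples),
#'     cfg$min_prevalent_samples)` samples, and
#' (b) its raw count is > 0 in at least one sample of every developmental
#'     stage present in `meta` (conditions pooled).
#' The prevalence criterion uses CPM on the full pre-filter library sizes;
#' the detection criterion deliberately uses raw counts, distinguishing
#' "expressed above threshold" from merely "detected".
#'
#' @param counts Validated count matrix.
#' @param meta Sample table matching `counts` (see [match_samples()]).
#' @param cfg A [run_config()].
#' @return List with `counts` (the filtered matrix) and `report`, a
#'   data frame with one row per input gene: `gene_id`, `retained` (0/1),
#'   `n_samples_passing_cpm`, `failed_stage` (first stage with no
#'   detection, empty string if none).
#' @export
filter_genes <- function(counts, meta, cfg = run_config()) {
  counts <- validate_counts(counts)
  meta <- match_samples(counts, meta)
  cpm <- compute_cpm(counts)
  n <- ncol(counts)
  need <- max(ceiling(cfg$prevalence_fraction * n),
              cfg$min_prevalent_samples)
  n_pass <- rowSums(cpm >= cfg$cpm_threshold)
  prevalent <- n_pass >= need

  stages <- levels(meta$stage)
  stages <- stages[stages %in% as.character(meta$stage)]
  # per stage: does each gene have a positive raw count in >= 1 sample?
  detected_by_stage <- vapply(stages, function(st) {
    rowSums(counts[, meta$stage == st, drop = FALSE] > 0) > 0
  }, logical(nrow(counts)))
  if (is.null(dim(detected_by_stage)))
    detected_by_stage <- matrix(detected_by_stage, nrow = nrow(counts),
                                dimnames = list(rownames(counts), stages))
  failed_stage <- apply(detected_by_stage, 1L, function(d) {
    i <- which(!d)
    if (length(i) == 0L) "" else stages[i[1L]]
  })
  detected_all <- failed_stage == ""
  keep <- prevalent & detected_all

  report <- data.frame(
    gene_id = rownames(counts),
    retained = as.integer(keep),
    n_samples_passing_cpm = as.integer(n_pass),
    failed_stage = failed_stage,
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(counts = counts[keep, , drop = FALSE], report = report)
}

#' Gene-wise Z-scores
#'
#' Centers and scales each gene's CPM row to mean 0 and sample standard
#' deviation 1 (denominator n - 1). Genes with zero variance carry no
#' trajectory information and are dropped and reported rather than
#' propagated as non-finite rows.
#'
#' @param cpm CPM matrix (genes x samples), typically post-filter.
#' @return List with `z` (the Z-score matrix) and `dropped` (character
#'   vector of zero-variance gene ids).
#' @export
zscore_genes <- function(cpm) {
  if (!is.matrix(cpm) || !is.numeric(cpm))
    stop_traj("cpm must be a numeric matrix")
  if (ncol(cpm) < 2L)
    stop_traj("Z-scoring needs at least 2 samples, got %d", ncol(cpm))
  mu <- rowMeans(cpm)
  sd <- apply(cpm, 1L, stats::sd)
  zero_var <- sd == 0 | !is.finite(sd)
  z <- (cpm[!zero_var, , drop = FALSE] - mu[!zero_var]) / sd[!zero_var]
  list(z = z, dropped = rownames(cpm)[zero_var])
}

#' Stage-mean trajectory profiles
#'
#' For one condition, averages each gene's Z-scores over the samples of
#' each developmental stage, yielding the genes-by-stages profile matrix
#' that is the clustering input. Stage columns follow the declared stage
#' order; every stage must contain at least one sample of the condition.
#'
#' @param z Z-score matrix (genes x samples).
#' @param meta Sample table covering the columns of `z`.
#' @param condition Condition label whose samples are averaged.
#' @return Numeric genes x stages matrix with class attribute
#'   `"stage_profiles"` and attribute `condition`.
#' @export
stage_profiles <- function(z, meta, condition) {
  if (!condition %in% levels(meta$condition))
    stop_traj("unknown condition '%s'", condition)
  meta <- meta[match(colnames(z), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop_traj("metadata does not cover every sample column of the Z matrix")
  sel <- meta$condition == condition
  stages <- levels(meta$stage)
  stages <- stages[stages %in% as.character(meta$stage)]
  empty <- stages[!stages %in% as.character(meta$stage[sel])]
  if (length(empty) > 0L)
    stop_traj("condition '%s' has no samples at stage(s): %s",
              condition, paste(empty, collapse = ", "))
  prof <- vapply(stages, function(st) {
    rowMeans(z[, sel & meta$stage == st, drop = FALSE])
  }, numeric(nrow(z)))
  if (is.null(dim(prof)))
    prof <- matrix(prof, nrow = nrow(z),
                   dimnames = list(rownames(z), stages))
  if (any(!is.finite(prof)))
    stop_traj("non-finite values in stage profiles for condition '%s'",
              condition)
  structure(prof, condition = condition, class = c("stage_profiles",
                                                   class(prof)))
}
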