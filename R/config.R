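#' Analysis run configuration
#'
#' Bundles the tunable parameters of the trajectory-clustering pipeline:
#' the expression filter (CPM threshold and sample prevalence), the k-means
#' sweep range and restart budget, the elbow gain threshold, and the master
#' RNG seed. Defaults follow common practice for bulk developmental
#' time-course data: genes must reach CPM >= 1 in at least 20% of samples
#' (never fewer than 2) and be detected in every developmental stage; the
#' cluster sweep covers k = 2..15 with 50 restarts of up to 1000 Lloyd
#' iterations each; the elbow rule accepts the first k whose next step
#' gains less than 5% of the current within-cluster sum of squares.
#'
#' @param cpm_threshold Minimum counts-per-million for a sample to count
#'   toward a gene's prevalence. Default 1.
#' @param prevalence_fraction Fraction of all samples that must reach
#'   `cpm_threshold`, in (0, 1]. Default 0.20.
#' @param min_prevalent_samples Absolute floor on the number of prevalent
#'   samples. Default 2.
#' @param k_min,k_max Range of cluster counts for the sweep. Defaults 2, 15.
#' @param n_restarts Random restarts per k. Default 50.
#' @param max_iter Maximum Lloyd iterations per restart. Default 1000.
#' @param gain_threshold Relative WCSS reduction, in (0, 1), below which an
#'   additional cluster is considered a diminishing return. Default 0.05.
#' @param log_transform Standardize `log2(CPM + 1)` rather than linear
#'   CPM (default `TRUE`). On the log scale, sequencing noise is roughly
#'   additive and comparable across expression levels, so a gene's
#'   standardized trajectory reflects its fold-change shape; standardizing
#'   linear CPM instead lets the highest-expression stage dominate both
#'   the shape and the noise.
#' @param zscore_scope Either `"pooled"` (Z-score each gene across all
#'   samples of both conditions, the default, so that both conditions'
#'   profiles share one scale) or `"per_condition"`.
#' @param seed Integer master seed for all stochastic steps.
#' @return A list of class `"traj_config"`.
#' @export
run_config <- function(cpm_threshold = 1,
                       prevalence_fraction = 0.20,
                       min_prevalent_samples = 2L,
                       k_min = 2L, k_max = 15L,
                       n_restarts = 50L, max_iter = 1000L,
                       gain_threshold = 0.05,
                       log_transform = TRUE,
                       zscore_scope = c("pooled", "per_condition"),
                       seed = 1L) {
  zscore_scope <- match.arg(zscore_scope)
  if (!is.logical(log_transform) || length(log_transform) != 1L)
    stop_traj("log_transform must be TRUE or FALSE")
  if (!is.numeric(cpm_threshold) || cpm_threshold <= 0)
    stop_traj("cpm_threshold must be a positive number")
  if (!is.numeric(prevalence_fraction) ||
      prevalence_fraction <= 0 || prevalence_fraction > 1)
    stop_traj("prevalence_fraction must lie in (0, 1]")
  if (min_prevalent_samples < 0)
    stop_traj("min_prevalent_samples must be non-negative")
  if (k_min < 1L) stop_traj("k_min must be >= 1")
  if (k_max < k_min) stop_traj("k_max must be >= k_min (got %d < %d)",
                               k_max, k_min)
  if (n_restarts < 1L) stop_traj("n_restarts must be >= 1")
  if (max_iter < 1L) stop_traj("max_iter must be >= 1")
  if (!is.numeric(gain_threshold) ||
      gain_threshold <= 0 || gain_threshold >= 1)
    stop_traj("gain_threshold must lie in (0, 1)")
  structure(list(
    cpm_threshold = cpm_threshold,
    prevalence_fraction = prevalence_fraction,
    min_prevalent_samples = as.integer(min_prevalent_samples),
    k_min = as.integer(k_min), k_max = as.integer(k_max),
    n_restarts = as.integer(n_restarts), max_iter = as.integer(max_iter),
    gain_threshold = gain_threshold,
    log_transform = log_transform,
    zscore_scope = zscore_scope,
    seed = as.integer(seed)
  ), class = "traj_config")
}

#' @export
print.traj_config <- function(x, ...) {
  cat("Trajectory analysis configuration\n")
  cat(sprintf("  filter: CPM >= %g in >= max(ceil(%g * n), %d) samples; detected in every stage\n",
              x$cpm_threshold, x$prevalence_fraction,
              x$min_prevalent_samples))
  cat(sprintf("  k-means: k = %d..%d, %d restarts, max %d iterations\n",
              x$k_min, x$k_max, x$n_restarts, x$max_iter))
  cat(sprintf("  elbow gain threshold: %g; Z of %s; scope: %s; seed: %d\n",
              x$gain_threshold,
              if (x$log_transform) "log2(CPM + 1)" else "linear CPM",
              x$zscore_scope, x$seed))
  invisible(x)
}
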