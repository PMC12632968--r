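# End-to-end orchestration: filter -> CPM -> Z -> reference stage
# profiles -> WCSS sweep -> elbow selection -> deterministic labels ->
# comparison profiles -> nearest-centroid projection -> transition table,
# with all tabular artifacts and a reproducibility manifest written to an
# output directory.

#' Run the full trajectory-clustering analysis
#'
#' Either file paths or in-memory objects may be supplied. Writes
#' `filter_report.tsv`, `wcss_curve.tsv`, `assignments.tsv`,
#' `centroids.tsv`, `transition.tsv`, `switched_genes.tsv`, a
#' `manifest.json` (config echo, seed, input checksums, per-stage gene
#' counts, selected k and gain table) and an append-only `run.log` to
#' `out_dir`.
#'
#' @param counts Count matrix, or path to a counts TSV.
#' @param meta Sample table, or path to a metadata TSV (then `stage_order`
#'   is required).
#' @param out_dir Output directory (created if missing).
#' @param cfg A [run_config()].
#' @param stage_order Stage labels in chronological order (required when
#'   `meta` is a path).
#' @param reference,comparison Condition labels; default to the first and
#'   second level of `meta$condition`.
#' @param k_override Optional fixed k; when given the WCSS sweep is
#'   skipped and this k is used directly.
#' @return Invisibly, a list with `filter`, `zscore`, `profiles_ref`,
#'   `profiles_cmp`, `sweep` (NULL under `k_override`), `selection`,
#'   `model`, `ref_assign`, `cmp_assign`, `transition`, `manifest`.
#' @export
run_trajectory_analysis <- function(counts, meta, out_dir,
                                    cfg = run_config(),
                                    stage_order = NULL,
                                    reference = NULL, comparison = NULL,
                                    k_override = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  checksums <- list()
  if (is.character(counts) && length(counts) == 1L) {
    checksums$counts <- unname(tools::md5sum(counts))
    counts <- read_counts(counts)
  }
  if (is.character(meta) && length(meta) == 1L) {
    if (is.null(stage_order))
      stop_traj("stage_order is required when metadata is read from a file")
    checksums$metadata <- unname(tools::md5sum(meta))
    meta <- read_sample_table(meta, stage_order)
  }
  counts <- validate_counts(counts)
  meta <- match_samples(counts, meta)
  if (is.null(reference)) reference <- levels(meta$condition)[1L]
  if (is.null(comparison)) comparison <- levels(meta$condition)[2L]
  if (is.na(comparison))
    stop_traj("metadata has a single condition; a comparison is required")
  log_line("input: %d genes x %d samples; reference = %s, comparison = %s; seed = %d",
           nrow(counts), ncol(counts), reference, comparison, cfg$seed)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line("stage '%s' failed: %s", name, conditionMessage(e))
      stop_traj("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  flt <- run_stage("filter", filter_genes(counts, meta, cfg))
  log_line("filter: %d of %d genes retained", nrow(flt$counts), nrow(counts))
  cpm <- run_stage("cpm", compute_cpm(counts)[rownames(flt$counts), ,
                                              drop = FALSE])
  expr <- if (cfg$log_transform) log2(cpm + 1) else cpm
  zs <- run_stage("zscore", {
    if (cfg$zscore_scope == "pooled") zscore_genes(expr)
    else {
      # per-condition Z, recombined on the genes finite in both
      parts <- lapply(levels(meta$condition), function(cd) {
        zscore_genes(expr[, meta$condition == cd, drop = FALSE])
      })
      keep <- Reduce(intersect, lapply(parts, function(p) rownames(p$z)))
      z <- do.call(cbind, lapply(parts, function(p) p$z[keep, , drop = FALSE]))
      z <- z[, colnames(expr)[colnames(expr) %in% colnames(z)], drop = FALSE]
      list(z = z, dropped = setdiff(rownames(expr), keep))
    }
  })
  log_line("zscore (%s): %d genes kept, %d zero-variance dropped",
           cfg$zscore_scope, nrow(zs$z), length(zs$dropped))

  prof_ref <- run_stage("profiles_reference",
                        stage_profiles(zs$z, meta, reference))
  prof_cmp <- run_stage("profiles_comparison",
                        stage_profiles(zs$z, meta, comparison))

  if (is.null(k_override)) {
    sweep_res <- run_stage("wcss_sweep", wcss_sweep(prof_ref, cfg))
    selection <- run_stage("select_k",
                           select_k(sweep_res$curve, cfg$gain_threshold))
    model <- sweep_res$models[[as.character(selection$k)]]
    log_line("sweep: k = %d..%d; selected k = %d (%s)",
             cfg$k_min, cfg$k_max, selection$k, selection$rationale)
  } else {
    sweep_res <- NULL
    selection <- list(k = as.integer(k_override), rationale = "override",
                      gains = NULL)
    model <- run_stage("kmeans_fit",
                       kmeans_fit(prof_ref, selection$k,
                                  n_restarts = cfg$n_restarts,
                                  max_iter = cfg$max_iter,
                                  seed = derive_seed(cfg$seed, selection$k)))
    log_line("sweep skipped; k forced to %d", selection$k)
  }
  model <- label_clusters(model)
  colnames(model$centers) <- colnames(prof_ref)

  ref_assign <- run_stage("assign_reference",
                          assign_to_centroids(prof_ref, model))
  cmp_assign <- run_stage("assign_comparison",
                          assign_to_centroids(prof_cmp, model))
  trans <- run_stage("transition",
                     transition_table(ref_assign, cmp_assign, k = model$k))
  log_line("transition: %d genes, %d switched cluster", trans$n_genes,
           nrow(trans$switched))

  # artifacts
  write_table(flt$report, file.path(out_dir, "filter_report.tsv"))
  if (!is.null(sweep_res))
    write_table(sweep_res$curve, file.path(out_dir, "wcss_curve.tsv"))
  assignments <- merge(
    stats::setNames(ref_assign[, c("gene_id", "cluster", "distance")],
                    c("gene_id", "ref_cluster", "distance_ref")),
    stats::setNames(cmp_assign[, c("gene_id", "cluster", "distance")],
                    c("gene_id", "cmp_cluster", "distance_cmp")),
    by = "gene_id")
  assignments <- assignments[order(assignments$gene_id), , drop = FALSE]
  write_table(assignments, file.path(out_dir, "assignments.tsv"))
  centroids <- model$centers
  rownames(centroids) <- seq_len(model$k)
  write_table(centroids, file.path(out_dir, "centroids.tsv"),
              id_column = "cluster")
  write_table(trans$counts, file.path(out_dir, "transition.tsv"),
              id_column = "ref_cluster")
  switched <- merge(trans$switched,
                    assignments[, c("gene_id", "distance_ref",
                                    "distance_cmp")],
                    by = "gene_id")
  switched <- switched[order(switched$ref_cluster, switched$cmp_cluster,
                             switched$gene_id), , drop = FALSE]
  write_table(switched, file.path(out_dir, "switched_genes.tsv"))

  manifest <- list(
    config = unclass(cfg),
    seed = cfg$seed,
    reference = reference, comparison = comparison,
    stage_order = levels(meta$stage),
    input_checksums = checksums,
    n_genes_input = nrow(counts),
    n_genes_filtered = nrow(flt$counts),
    n_genes_clustered = nrow(zs$z),
    selected_k = selection$k,
    selection_rationale = selection$rationale,
    gains = selection$gains,
    n_switched = nrow(trans$switched)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done; artifacts in %s", out_dir)
  invisible(list(filter = flt, zscore = zs, profiles_ref = prof_ref,
                 profiles_cmp = prof_cmp, sweep = sweep_res,
                 selection = selection, model = model,
                 ref_assign = ref_assign, cmp_assign = cmp_assign,
                 transition = trans, manifest = manifest))
}

#' Run the delta-delta-Ct analysis on a Ct table file
#'
#' @param ct_path Path to a Ct TSV with columns `sample_id`, `target`,
#'   `replicate`, `ct`, `group`.
#' @param out_dir Output directory; `ratios.tsv` and `group_stats.tsv`
#'   are written there.
#' @inheritParams ddct_ratio
#' @return Invisibly, the [ddct_ratio()] result.
#' @export
run_ddct <- function(ct_path, out_dir, nuclear_target = "18S",
                     reference_group = NULL) {
  ct <- utils::read.delim(ct_path, sep = "\t", stringsAsFactors = FALSE)
  res <- ddct_ratio(ct, nuclear_target = nuclear_target,
                    reference_group = reference_group)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(res$ratios, file.path(out_dir, "ratios.tsv"))
  write_table(res$group_stats, file.path(out_dir, "group_stats.tsv"))
  invisible(res)
}

#' Run the methylation summary on a bisulfite count file
#'
#' @param mc_path Path to a methylation-counts TSV with columns
#'   `amplicon`, `cpg_index`, `methylated`, `unmethylated`, `sample_id`,
#'   `group`.
#' @param out_dir Output directory; `methylation_percent.tsv` (per
#'   amplicon and sample) and `methylation_group_means.tsv` are written.
#' @inheritParams methylation_summary
#' @return Invisibly, the [methylation_summary()] result.
#' @export
run_methylation <- function(mc_path, out_dir, min_coverage = 10L) {
  mc <- utils::read.delim(mc_path, sep = "\t", stringsAsFactors = FALSE)
  res <- methylation_summary(mc, min_coverage = min_coverage)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(res$per_amplicon,
              file.path(out_dir, "methylation_percent.tsv"))
  write_table(res$group_means,
              file.path(out_dir, "methylation_group_means.tsv"))
  invisible(res)
}
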