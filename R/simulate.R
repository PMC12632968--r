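# Synthetic data generators: negative-binomial counts with planted
# trajectory archetypes and condition-specific archetype switching, plus
# qPCR Ct tables and bisulfite amplicon counts with known truth. Every
# generator is a pure function of its design and seed.

#' Default trajectory archetype library
#'
#' Stage-trajectory shapes used as planted cluster means, on the log-mean
#' scale. Shapes are unit-norm, zero-mean stage vectors taken at evenly
#' spaced angles in the two-dimensional "shape plane" orthogonal to the
#' constant vector, spanned by a linear and a quadratic stage contrast.
#' With the default nine archetypes this covers the qualitative repertoire
#' of developmental trajectories — monotone increase and decrease, early
#' and late onset, transient peaks and dips — while maximizing the minimum
#' pairwise separation between shapes. Because the pipeline standardizes
#' log-scale expression, these log-scale shapes are what the clustering
#' sees, up to a common scale and sampling noise.
#'
#' @param n_stages Number of developmental stages (>= 3). Default 3.
#' @param n_archetypes Number of shapes. Default 9.
#' @return Numeric `n_archetypes` x `n_stages` matrix, rows unit-norm and
#'   zero-mean.
#' @export
default_archetypes <- function(n_stages = 3L, n_archetypes = 9L) {
  if (n_stages < 3L) stop_traj("need at least 3 stages for trajectory shapes")
  t <- seq_len(n_stages)
  e1 <- t - mean(t)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- (t - mean(t))^2
  e2 <- e2 - mean(e2)
  e2 <- e2 - sum(e2 * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  theta <- 2 * pi * (seq_len(n_archetypes) - 1L) / n_archetypes
  arch <- outer(cos(theta), e1) + outer(sin(theta), e2)
  rownames(arch) <- paste0("archetype", seq_len(n_archetypes))
  arch
}

#' Simulation design for planted-trajectory count data
#'
#' Describes a two-condition developmental time course: ordered stages,
#' samples per stage per condition, a library of trajectory archetypes in
#' Z-units, genes per archetype, the fraction of genes whose archetype
#' differs in the comparison condition, the amplitude with which
#' archetypes modulate the log mean, the gene baseline distribution, the
#' negative-binomial dispersion, and the sample library-size interval.
#' Defaults mirror a 3-stage bulk design with 6 individuals per stage and
#' condition, nine archetypes of 200 genes, amplitude 2, dispersion 0.1
#' and a 10% switch fraction.
#'
#' @param stage_labels Ordered stage labels.
#' @param samples_per_stage Samples per stage per condition.
#' @param conditions Two condition labels, reference first.
#' @param archetypes Archetype matrix (shapes x stages) in Z-units; see
#'   [default_archetypes()].
#' @param genes_per_archetype Genes planted per archetype.
#' @param switch_fraction Fraction of genes in `[0, 1)` whose comparison-
#'   condition archetype differs from their reference archetype.
#' @param amplitude Multiplier applied to archetype values on the log-mean
#'   scale.
#' @param baseline_log_mean,baseline_log_sd Normal distribution of gene
#'   baseline log means.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param library_size_range Positive interval; sample library sizes are
#'   drawn log-uniformly from it and enter as relative size factors.
#' @param seed Integer seed.
#' @return List of class `"sim_design"`.
#' @export
sim_design <- function(stage_labels = c("E18.5", "12wk", "39wk"),
                       samples_per_stage = 6L,
                       conditions = c("Natural", "IVF"),
                       archetypes = default_archetypes(length(stage_labels)),
                       genes_per_archetype = 200L,
                       switch_fraction = 0.1,
                       amplitude = 2,
                       baseline_log_mean = log(100),
                       baseline_log_sd = 1,
                       nb_dispersion = 0.1,
                       library_size_range = c(5e5, 2e6),
                       seed = 1L) {
  archetypes <- as.matrix(archetypes)
  if (ncol(archetypes) != length(stage_labels))
    stop_traj("archetypes have %d stages but %d stage labels were given",
              ncol(archetypes), length(stage_labels))
  if (anyDuplicated(archetypes) > 0L)
    stop_traj("archetype vectors must be distinct")
  if (length(conditions) != 2L || anyDuplicated(conditions))
    stop_traj("exactly two distinct conditions are required")
  if (samples_per_stage < 1L) stop_traj("samples_per_stage must be >= 1")
  if (genes_per_archetype < 1L) stop_traj("genes_per_archetype must be >= 1")
  if (switch_fraction < 0 || switch_fraction >= 1)
    stop_traj("switch_fraction must lie in [0, 1)")
  if (nb_dispersion < 0) stop_traj("nb_dispersion must be >= 0")
  if (length(library_size_range) != 2L || any(library_size_range <= 0) ||
      diff(library_size_range) < 0)
    stop_traj("library_size_range must be a positive increasing interval")
  structure(list(
    stage_labels = as.character(stage_labels),
    samples_per_stage = as.integer(samples_per_stage),
    conditions = as.character(conditions),
    archetypes = archetypes,
    genes_per_archetype = as.integer(genes_per_archetype),
    switch_fraction = switch_fraction,
    amplitude = amplitude,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    nb_dispersion = nb_dispersion,
    library_size_range = library_size_range,
    seed = as.integer(seed)
  ), class = "sim_design")
}

#' Simulate a planted-trajectory count data set
#'
#' Draws gene baselines, sample library sizes, condition-specific
#' archetype switches and negative-binomial counts from the design. Gene
#' g of archetype a in condition c at stage t has mean
#' `mu = exp(b_g + amplitude * archetype_{a(g,c)}[t]) * libsize_s /
#' median(libsize)` and counts are negative-binomial with that mean and
#' the design dispersion. Reference-condition genes always use their
#' source archetype; switched genes use their switch-target archetype in
#' the comparison condition.
#'
#' @param design A [sim_design()].
#' @return List with `counts` (gene x sample integer matrix), `samples`
#'   (sample table as from [make_sample_table()]), and `truth`, a list of
#'   `genes` (`gene_id`, `archetype_ref`, `archetype_cmp`, `is_switched`)
#'   and `samples` (`sample_id`, `stage`, `condition`, `library_size`).
#' @export
simulate_counts <- function(design = sim_design()) {
  if (!inherits(design, "sim_design")) stop_traj("design must be a sim_design")
  d <- design
  n_arch <- nrow(d$archetypes)
  n_genes <- n_arch * d$genes_per_archetype
  n_stages <- length(d$stage_labels)
  n_per_cond <- n_stages * d$samples_per_stage

  sample_meta <- do.call(rbind, lapply(d$conditions, function(cond) {
    do.call(rbind, lapply(seq_len(n_stages), function(ti) {
      data.frame(
        sample_id = sprintf("%s_%s_r%d", cond, d$stage_labels[ti],
                            seq_len(d$samples_per_stage)),
        stage = d$stage_labels[ti], condition = cond,
        replicate = sprintf("r%d", seq_len(d$samples_per_stage)),
        stringsAsFactors = FALSE)
    }))
  }))
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  arch_ref <- rep(seq_len(n_arch), each = d$genes_per_archetype)

  res <- with_seed(d$seed, {
    b <- stats::rnorm(n_genes, d$baseline_log_mean, d$baseline_log_sd)
    lib <- exp(stats::runif(2L * n_per_cond,
                            log(d$library_size_range[1L]),
                            log(d$library_size_range[2L])))
    n_switch <- floor(d$switch_fraction * n_genes)
    switched_idx <- if (n_switch > 0L) sort(sample.int(n_genes, n_switch))
                    else integer(0)
    arch_cmp <- arch_ref
    if (n_switch > 0L) {
      arch_cmp[switched_idx] <- vapply(arch_ref[switched_idx], function(a) {
        sample(setdiff(seq_len(n_arch), a), 1L)
      }, integer(1L))
    }
    sf <- lib / stats::median(lib)
    stage_idx <- match(sample_meta$stage, d$stage_labels)
    is_cmp <- sample_meta$condition == d$conditions[2L]
    counts <- matrix(0L, nrow = n_genes, ncol = nrow(sample_meta),
                     dimnames = list(gene_ids, sample_meta$sample_id))
    for (s in seq_len(nrow(sample_meta))) {
      a <- if (is_cmp[s]) arch_cmp else arch_ref
      mu <- exp(b + d$amplitude * d$archetypes[cbind(a, stage_idx[s])]) * sf[s]
      counts[, s] <- if (d$nb_dispersion > 0)
        stats::rnbinom(n_genes, mu = mu, size = 1 / d$nb_dispersion)
      else
        stats::rpois(n_genes, mu)
    }
    list(counts = counts, lib = lib, arch_cmp = arch_cmp)
  })

  samples <- make_sample_table(sample_meta, stage_order = d$stage_labels,
                               conditions = d$conditions)
  truth_genes <- data.frame(
    gene_id = gene_ids, archetype_ref = arch_ref,
    archetype_cmp = res$arch_cmp,
    is_switched = arch_ref != res$arch_cmp,
    stringsAsFactors = FALSE)
  truth_samples <- data.frame(
    sample_id = sample_meta$sample_id, stage = sample_meta$stage,
    condition = sample_meta$condition, library_size = res$lib,
    stringsAsFactors = FALSE)
  list(counts = res$counts, samples = samples,
       truth = list(genes = truth_genes, samples = truth_samples))
}

#' Simulate a qPCR Ct table with a known copy-number effect
#'
#' Reference-group samples have a fixed true dCt (mitochondrial minus
#' nuclear cycles); comparison groups are shifted by `effect_log2` cycles,
#' so their true relative ratio is `2^(-effect_log2)`. Gaussian replicate
#' noise with `noise_sd` cycles is added to every measured Ct.
#'
#' @param groups Named integer vector of samples per group, reference
#'   group first, e.g. `c(Natural = 6, IVF = 6)`.
#' @param effect_log2 True dCt shift of each non-reference group relative
#'   to the reference, in cycles (log2 units). Scalar or one value per
#'   non-reference group.
#' @param noise_sd Replicate noise standard deviation in cycles (>= 0).
#' @param seed Integer seed.
#' @param mt_target,nuclear_target Target labels. Defaults "ND1", "18S".
#' @param n_replicates Technical replicates per (sample, target).
#'   Default 3.
#' @param base_nuclear_ct,base_delta_ct True nuclear Ct and reference-group
#'   dCt. Defaults 14 and -5 (mitochondrial genomes outnumber nuclear).
#' @return Data frame `sample_id`, `target`, `replicate`, `ct`, `group`.
#' @export
simulate_ct <- function(groups, effect_log2 = 0, noise_sd = 0.2, seed = 1L,
                        mt_target = "ND1", nuclear_target = "18S",
                        n_replicates = 3L,
                        base_nuclear_ct = 14, base_delta_ct = -5) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop_traj("groups must be a named vector of sample counts")
  if (noise_sd < 0) stop_traj("noise_sd must be >= 0")
  other <- names(groups)[-1L]
  effects <- c(0, rep_len(effect_log2, length(other)))
  names(effects) <- names(groups)
  with_seed(seed, {
    rows <- list()
    for (g in names(groups)) {
      for (i in seq_len(groups[[g]])) {
        sid <- sprintf("%s_s%02d", g, i)
        true_dct <- base_delta_ct + effects[[g]]
        for (r in seq_len(n_replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid,
            target = c(mt_target, nuclear_target),
            replicate = r,
            ct = c(base_nuclear_ct + true_dct, base_nuclear_ct) +
              stats::rnorm(2L, 0, noise_sd),
            group = g, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate targeted bisulfite amplicon counts
#'
#' Per CpG, coverage is Poisson with mean `coverage_mean` and methylated
#' reads are binomial with the group's true methylation probability.
#'
#' @param amplicons Named integer vector: amplicon label -> number of CpGs.
#' @param true_percent Named list, one element per group, each a numeric
#'   vector of true percent methylation per amplicon (named by amplicon,
#'   values in `[0, 100]`).
#' @param coverage_mean Mean per-CpG read coverage.
#' @param samples_per_group Samples simulated per group. Default 5.
#' @param seed Integer seed.
#' @return Data frame `amplicon`, `cpg_index`, `methylated`,
#'   `unmethylated`, `sample_id`, `group`.
#' @export
simulate_bisulfite <- function(amplicons, true_percent, coverage_mean = 100,
                               samples_per_group = 5L, seed = 1L) {
  if (is.null(names(amplicons)))
    stop_traj("amplicons must be a named vector (amplicon -> n CpGs)")
  if (!is.list(true_percent) || is.null(names(true_percent)))
    stop_traj("true_percent must be a named list, one element per group")
  for (g in names(true_percent)) {
    p <- true_percent[[g]]
    if (any(p < 0 | p > 100))
      stop_traj("true percents must lie in [0, 100] (group '%s')", g)
    if (!all(names(amplicons) %in% names(p)))
      stop_traj("group '%s' lacks a true percent for some amplicon", g)
  }
  with_seed(seed, {
    rows <- list()
    for (g in names(true_percent)) {
      for (i in seq_len(samples_per_group)) {
        sid <- sprintf("%s_s%02d", g, i)
        for (amp in names(amplicons)) {
          ncpg <- amplicons[[amp]]
          cov <- stats::rpois(ncpg, coverage_mean)
          meth <- stats::rbinom(ncpg, cov, true_percent[[g]][[amp]] / 100)
          rows[[length(rows) + 1L]] <- data.frame(
            amplicon = amp, cpg_index = seq_len(ncpg),
            methylated = meth, unmethylated = cov - meth,
            sample_id = sid, group = g, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
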