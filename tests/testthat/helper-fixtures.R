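# Fixture builders used across test files. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

random_counts <- function(n_genes, n_samples, seed = 1, max_count = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, max_count / 2),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "double"
  m
}

two_condition_meta <- function(n_samples, stages = c("E18.5", "12wk", "39wk"),
                               conditions = c("Natural", "IVF")) {
  # round-robin stage x condition layout over the samples
  stopifnot(n_samples %% (length(stages) * length(conditions)) == 0)
  grid <- expand.grid(stage = stages, condition = conditions,
                      stringsAsFactors = FALSE)
  reps <- n_samples / nrow(grid)
  df <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n_samples)),
    stage = rep(grid$stage, each = reps),
    condition = rep(grid$condition, each = reps),
    replicate = sprintf("r%d", sequence(rep(reps, nrow(grid)))),
    stringsAsFactors = FALSE
  )
  make_sample_table(df, stage_order = stages, conditions = conditions)
}

# profiles drawn around planted centroids with isotropic Gaussian noise
planted_profiles <- function(centroids, n_per, noise_sd, seed = 1) {
  set.seed(seed)
  k <- nrow(centroids); d <- ncol(centroids)
  lab <- rep(seq_len(k), each = n_per)
  x <- centroids[lab, , drop = FALSE] +
    matrix(rnorm(length(lab) * d, 0, noise_sd), ncol = d)
  rownames(x) <- sprintf("g%04d", seq_along(lab))
  colnames(x) <- colnames(centroids)
  list(profiles = x, labels = lab)
}

# run the in-memory analysis chain up to stage profiles for one condition
sim_profiles <- function(sim, cfg, condition) {
  flt <- filter_genes(sim$counts, sim$samples, cfg)
  cpm <- compute_cpm(sim$counts)[rownames(flt$counts), , drop = FALSE]
  expr <- if (cfg$log_transform) log2(cpm + 1) else cpm
  zs <- zscore_genes(expr)
  stage_profiles(zs$z, sim$samples, condition)
}
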