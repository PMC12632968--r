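# Seeded multi-restart Lloyd k-means over stage-mean profiles, the WCSS
# sweep, the elbow selection rule and deterministic cluster labelling.
#
# The clustering is implemented here rather than delegated because its
# semantics are part of the method's contract: restarts draw k distinct
# data rows uniformly from a seeded generator, nearest-centroid ties break
# toward the lowest centroid index, and an emptied cluster is repaired by
# reseeding it with the point farthest from its current centroid, so runs
# are bit-reproducible from the seed alone.

#' Fit k-means to trajectory profiles
#'
#' Lloyd's algorithm with squared-Euclidean distance, `n_restarts`
#' independent seeded initializations (each drawing k distinct profile
#' rows uniformly at random as initial centers), and the best restart by
#' within-cluster sum of squares returned.
#'
#' @param profiles Numeric genes x stages matrix.
#' @param k Number of clusters; must not exceed the number of distinct
#'   profile rows.
#' @param n_restarts Number of random restarts (>= 1).
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param seed Integer seed controlling all restarts.
#' @return A list of class `"traj_kmeans"`: `k`, `centers` (k x stages),
#'   `cluster` (named integer vector, gene -> 1..k), `wcss`, `seed`,
#'   `n_restarts`, `iterations` (of the winning restart), `converged`.
#' @export
kmeans_fit <- function(profiles, k, n_restarts = 50L, max_iter = 1000L,
                       seed = 1L) {
  x <- as.matrix(profiles)
  n <- nrow(x)
  if (n < 1L) stop_traj("no profiles to cluster")
  if (n_restarts < 1L) stop_traj("n_restarts must be >= 1")
  distinct <- !duplicated(x)
  n_distinct <- sum(distinct)
  if (k > n_distinct)
    stop_traj("k = %d exceeds the number of distinct profiles (%d)",
              k, n_distinct)
  distinct_idx <- which(distinct)

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- x[sample(distinct_idx, k), , drop = FALSE]
      fit <- lloyd_once(x, init, max_iter)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
  })
  cl <- best$cluster
  names(cl) <- rownames(x)
  structure(list(
    k = as.integer(k),
    centers = best$centers,
    cluster = cl,
    wcss = best$wcss,
    seed = as.integer(seed),
    n_restarts = as.integer(n_restarts),
    iterations = best$iterations,
    converged = best$converged
  ), class = "traj_kmeans")
}

# One Lloyd run from given initial centers. Ties in nearest centroid go to
# the lowest centroid index (max.col on negated distances, ties "first");
# an empty cluster is reseeded with the point currently farthest from its
# assigned centroid.
lloyd_once <- function(x, centers, max_iter) {
  n <- nrow(x); k <- nrow(centers)
  assign_old <- integer(n)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- sq_dist_to_centers(x, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    # repair empty clusters before the update step
    repeat {
      sizes <- tabulate(assign_new, nbins = k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      cur <- d2[cbind(seq_len(n), assign_new)]
      # exclude singletons from donation so repair cannot cascade to empty
      cur[sizes[assign_new] <= 1L] <- -Inf
      far <- which.max(cur)
      assign_new[far] <- empty[1L]
    }
    if (identical(assign_new, assign_old)) { converged <- TRUE; break }
    assign_old <- assign_new
    centers <- rowsum(x, assign_new) / tabulate(assign_new, nbins = k)
    if (iter >= max_iter) break
  }
  d2 <- sq_dist_to_centers(x, centers)
  wcss <- sum(d2[cbind(seq_len(n), assign_old)])
  rownames(centers) <- NULL
  list(centers = centers, cluster = assign_old, wcss = wcss,
       iterations = iter, converged = converged)
}

#' @export
print.traj_kmeans <- function(x, ...) {
  cat(sprintf("k-means trajectory model: k = %d, %d genes, WCSS = %.4f (%d restarts, seed %d)\n",
              x$k, length(x$cluster), x$wcss, x$n_restarts, x$seed))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Sweep cluster counts and record the WCSS curve
#'
#' Runs [kmeans_fit()] for every k in `cfg$k_min .. cfg$k_max`. Each k
#' receives its own sub-seed derived from `cfg$seed` via [derive_seed()],
#' so extending the sweep range never perturbs the other fits.
#'
#' @param profiles Numeric genes x stages matrix.
#' @param cfg A [run_config()].
#' @return List with `curve` (data frame `k`, `wcss`, `gain`, where
#'   `gain[i] = (wcss[i-1] - wcss[i]) / wcss[i-1]` and the first gain is
#'   `NA`) and `models` (list of `"traj_kmeans"`, named by k).
#' @export
wcss_sweep <- function(profiles, cfg = run_config()) {
  ks <- seq.int(cfg$k_min, cfg$k_max)
  models <- lapply(ks, function(k) {
    kmeans_fit(profiles, k,
               n_restarts = cfg$n_restarts, max_iter = cfg$max_iter,
               seed = derive_seed(cfg$seed, k))
  })
  names(models) <- as.character(ks)
  wcss <- vapply(models, `[[`, numeric(1L), "wcss")
  gain <- c(NA_real_, (wcss[-length(wcss)] - wcss[-1L]) /
                        wcss[-length(wcss)])
  curve <- data.frame(k = ks, wcss = unname(wcss), gain = unname(gain))
  list(curve = curve, models = models)
}

#' Select the cluster count by the elbow rule
#'
#' Returns the smallest k for which adding one more cluster reduces the
#' within-cluster sum of squares by less than `gain_threshold` of its
#' current value, i.e. the smallest k beyond which additional clusters
#' yield diminishing returns. If every step gains at least the threshold
#' the largest swept k is returned with rationale `"no-elbow"`.
#'
#' @param curve Data frame with columns `k`, `wcss` (and optionally
#'   `gain`), as produced by [wcss_sweep()].
#' @param gain_threshold Relative gain threshold in (0, 1). Default 0.05.
#' @return List with `k` (the selection), `rationale` (`"elbow"` or
#'   `"no-elbow"`), and `gains` (data frame `k`, `gain` for each step,
#'   where the gain at k is the relative reduction achieved by moving from
#'   k - 1 to k).
#' @export
select_k <- function(curve, gain_threshold = 0.05) {
  if (!all(c("k", "wcss") %in% names(curve)))
    stop_traj("curve must have columns k and wcss")
  if (nrow(curve) < 2L) stop_traj("curve needs at least 2 entries")
  o <- order(curve$k)
  ks <- curve$k[o]; w <- curve$wcss[o]
  if (w[1L] <= 0) stop_traj("wcss at the smallest k must be positive")
  up <- w[-1L] > w[-length(w)] * (1 + 1e-9) + 1e-9
  if (any(up))
    stop_traj("WCSS curve increases at k = %s; increase n_restarts",
              paste(ks[-1L][up], collapse = ", "))
  gain <- (w[-length(w)] - w[-1L]) / w[-length(w)]
  gains <- data.frame(k = ks[-1L], gain = gain)
  # gain at ks[i+1] is the reduction from ks[i] -> ks[i+1]
  hit <- which(gain < gain_threshold)
  if (length(hit) == 0L) {
    list(k = ks[length(ks)], rationale = "no-elbow", gains = gains)
  } else {
    list(k = ks[hit[1L]], rationale = "elbow", gains = gains)
  }
}

#' Relabel clusters deterministically
#'
#' Orders clusters by their centroid value at the first stage (ascending),
#' breaking ties by cluster size (descending), and renames them 1..k.
#' Purely a permutation: assignments, centroids and WCSS are unchanged up
#' to the relabelling.
#'
#' @param model A `"traj_kmeans"` model.
#' @return The relabelled model.
#' @export
label_clusters <- function(model) {
  k <- model$k
  sizes <- tabulate(model$cluster, nbins = k)
  ord <- order(model$centers[, 1L], -sizes)
  # ord[new] = old; build old -> new map
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  model$centers <- model$centers[ord, , drop = FALSE]
  model$cluster[] <- relabel[model$cluster]
  model
}
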