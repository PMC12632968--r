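# Projection of a comparison condition onto reference-trained centroids,
# transition (alluvial) tables of cluster switching, and gene-set
# intersections.

#' Assign profiles to the nearest trained centroid
#'
#' Projects stage-mean profiles (typically the comparison condition's)
#' onto the centroids of a reference-trained model: each gene goes to the
#' centroid with the smallest squared Euclidean distance, ties breaking
#' toward the lowest cluster label. The profiles' stage columns must match
#' the model's stages exactly — trajectories are only comparable on the
#' same ordered stage axis.
#'
#' @param profiles Numeric genes x stages matrix.
#' @param model A `"traj_kmeans"` model whose centroid columns carry the
#'   same stage names in the same order.
#' @return Data frame `gene_id`, `cluster`, `distance` (squared Euclidean
#'   to the assigned centroid).
#' @export
assign_to_centroids <- function(profiles, model) {
  x <- as.matrix(profiles)
  ps <- colnames(x); ms <- colnames(model$centers)
  if (!is.null(ps) && !is.null(ms) && !identical(ps, ms))
    stop_traj("stage columns differ between profiles [%s] and model [%s]",
              paste(ps, collapse = ", "), paste(ms, collapse = ", "))
  if (ncol(x) != ncol(model$centers))
    stop_traj("profiles have %d stages but the model has %d",
              ncol(x), ncol(model$centers))
  d2 <- sq_dist_to_centers(x, model$centers)
  cl <- max.col(-d2, ties.method = "first")
  data.frame(
    gene_id = rownames(x),
    cluster = cl,
    distance = d2[cbind(seq_len(nrow(x)), cl)],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Tabulate cluster-membership transitions between conditions
#'
#' Crosses reference-condition cluster assignments against comparison-
#' condition assignments over their shared gene universe, producing the
#' k x k count table behind an alluvial plot, plus the off-diagonal
#' (switched) genes. Genes present in only one assignment are excluded and
#' reported.
#'
#' @param ref_assign,cmp_assign Data frames with columns `gene_id` and
#'   `cluster` (as returned by [assign_to_centroids()]), or named integer
#'   vectors.
#' @param k Number of clusters; defaults to the largest label observed.
#' @return List of class `"transition_table"`: `counts` (k x k integer
#'   matrix, rows = reference clusters, columns = comparison clusters),
#'   `switched` (data frame `gene_id`, `ref_cluster`, `cmp_cluster` for
#'   off-diagonal genes), `excluded` (gene ids absent from one side),
#'   `n_genes` (size of the shared universe).
#' @export
transition_table <- function(ref_assign, cmp_assign, k = NULL) {
  ref <- as_assignment(ref_assign, "ref_assign")
  cmp <- as_assignment(cmp_assign, "cmp_assign")
  shared <- intersect(names(ref), names(cmp))
  if (length(shared) == 0L)
    stop_traj("the two assignments share no genes")
  excluded <- union(setdiff(names(ref), shared), setdiff(names(cmp), shared))
  r <- ref[shared]; c_ <- cmp[shared]
  if (is.null(k)) k <- max(r, c_)
  counts <- table(factor(r, levels = seq_len(k)),
                  factor(c_, levels = seq_len(k)))
  counts <- matrix(as.integer(counts), nrow = k,
                   dimnames = list(ref_cluster = seq_len(k),
                                   cmp_cluster = seq_len(k)))
  off <- r != c_
  switched <- data.frame(
    gene_id = shared[off],
    ref_cluster = unname(r[off]),
    cmp_cluster = unname(c_[off]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  switched <- switched[order(switched$ref_cluster, switched$cmp_cluster,
                             switched$gene_id), , drop = FALSE]
  rownames(switched) <- NULL
  structure(list(counts = counts, switched = switched,
                 excluded = sort(excluded), n_genes = length(shared)),
            class = "transition_table")
}

as_assignment <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("gene_id", "cluster") %in% names(x)))
      stop_traj("%s must have columns gene_id and cluster", what)
    out <- as.integer(x$cluster)
    names(out) <- as.character(x$gene_id)
  } else if (is.numeric(x) && !is.null(names(x))) {
    out <- as.integer(x)
    names(out) <- names(x)
  } else {
    stop_traj("%s must be a data frame or a named integer vector", what)
  }
  if (anyDuplicated(names(out)))
    stop_traj("%s contains duplicate gene ids", what)
  out
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("Cluster transition table: %d genes, %d switched (%.1f%%), %d excluded\n",
              x$n_genes, nrow(x$switched),
              100 * nrow(x$switched) / x$n_genes, length(x$excluded)))
  print(x$counts)
  invisible(x)
}

#' Disjoint intersection regions of 2-3 gene sets
#'
#' Partitions the union of the named sets into the disjoint regions of a
#' Venn diagram: every non-empty combination of memberships, with counts
#' and member lists in deterministic order.
#'
#' @param sets Named list of 2 or 3 character vectors; duplicates within a
#'   set are removed (case-sensitively).
#' @return List with `regions`, a data frame `region` (set names joined by
#'   "&"), `count`; and `members`, a list of sorted gene vectors named by
#'   region. Regions are ordered by the sets they involve, single sets
#'   first in input order, then pairs, then the triple.
#' @export
intersect_gene_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L)
    stop_traj("sets must be a named list of 2 or 3 gene vectors")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)))
    stop_traj("every set must have a non-empty name")
  if (anyDuplicated(nm))
    stop_traj("set names must be unique")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (is.null(dim(member)))
    member <- matrix(member, nrow = length(universe))
  n <- length(sets)
  combos <- list()
  for (size in seq_len(n)) {
    idx <- utils::combn(n, size, simplify = FALSE)
    combos <- c(combos, idx)
  }
  regions <- lapply(combos, function(ix) {
    inside <- rowSums(member[, ix, drop = FALSE]) == length(ix)
    outside <- if (length(ix) == n) rep(FALSE, length(universe))
               else rowSums(member[, -ix, drop = FALSE]) > 0
    universe[inside & !outside]
  })
  labels <- vapply(combos, function(ix) paste(nm[ix], collapse = "&"),
                   character(1L))
  names(regions) <- labels
  list(
    regions = data.frame(region = labels,
                         count = vapply(regions, length, integer(1L)),
                         stringsAsFactors = FALSE, row.names = NULL),
    members = regions
  )
}
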