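# Reading, validating and writing the pipeline's tabular formats.
# All files are tab-separated UTF-8 with "." as the decimal separator;
# gzip-compressed inputs are read transparently.

#' Validate a count matrix
#'
#' Checks that `counts` is a gene x sample matrix of non-negative integral
#' values with unique, non-empty row (gene) and column (sample) names, at
#' least one gene and at least two samples.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns.
#' @return The validated matrix (storage mode integer-compatible numeric),
#'   invisibly unchanged in content.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_traj("counts must be a numeric matrix")
  if (nrow(counts) < 1L) stop_traj("count matrix has no genes")
  if (ncol(counts) < 2L) stop_traj("count matrix needs at least 2 samples")
  gid <- rownames(counts); sid <- colnames(counts)
  if (is.null(gid) || any(!nzchar(gid)))
    stop_traj("count matrix must have non-empty gene (row) names")
  if (is.null(sid) || any(!nzchar(sid)))
    stop_traj("count matrix must have non-empty sample (column) names")
  if (anyDuplicated(gid))
    stop_traj("duplicate gene id(s): %s",
              paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop_traj("duplicate sample id(s): %s",
              paste(unique(sid[duplicated(sid)]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop_traj("invalid count %s at gene '%s', sample '%s' (row %d, column %d): counts must be non-negative integers",
              format(counts[b[1L], b[2L]]), gid[b[1L]], sid[b[2L]],
              b[1L], b[2L])
  }
  storage.mode(counts) <- "double"
  counts
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers
#' and whose header row holds sample identifiers. Row and column order are
#' preserved. Gzip-compressed files are accepted transparently.
#'
#' @param path Path to the TSV (optionally .gz).
#' @return Validated numeric matrix with gene row names and sample column
#'   names.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop_traj("count file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop_traj("count file '%s' is empty or has no sample columns", path)
  gid <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop_traj("count file '%s' contains non-numeric entries", path)
  rownames(m) <- gid
  validate_counts(m)
}

#' Read a sample metadata table
#'
#' Expects columns `sample_id`, `stage`, `condition`, `replicate`. The
#' developmental stage is coded as an ordered factor following
#' `stage_order` exactly; stage order is never inferred from the file
#' because labels such as "E18.5" and "12wk" do not sort textually.
#'
#' @param path Path to the metadata TSV.
#' @param stage_order Character vector giving the developmental stages in
#'   chronological order.
#' @param conditions Optional character vector of condition levels, the
#'   first being the reference (training) condition. Defaults to the
#'   conditions in file order of first appearance.
#' @return A `data.frame` with `sample_id`, ordered `stage`, `condition`
#'   factor and `replicate`.
#' @export
read_sample_table <- function(path, stage_order, conditions = NULL) {
  if (!file.exists(path)) stop_traj("metadata file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  make_sample_table(df, stage_order, conditions)
}

#' Build a validated sample table from a data frame
#'
#' @param df Data frame with columns `sample_id`, `stage`, `condition`,
#'   `replicate`.
#' @inheritParams read_sample_table
#' @return A validated `data.frame` (see [read_sample_table()]).
#' @export
make_sample_table <- function(df, stage_order, conditions = NULL) {
  need <- c("sample_id", "stage", "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_traj("metadata is missing required column(s): %s",
              paste(miss, collapse = ", "))
  if (missing(stage_order) || length(stage_order) < 1L)
    stop_traj("stage_order must be supplied explicitly")
  if (anyDuplicated(df$sample_id))
    stop_traj("duplicate sample id(s) in metadata: %s",
              paste(unique(df$sample_id[duplicated(df$sample_id)]),
                    collapse = ", "))
  unknown <- setdiff(unique(as.character(df$stage)), stage_order)
  if (length(unknown) > 0L)
    stop_traj("stage label(s) not in stage_order: %s",
              paste(unknown, collapse = ", "))
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    stage = factor(as.character(df$stage),
                   levels = stage_order, ordered = TRUE),
    condition = NA, replicate = as.character(df$replicate),
    stringsAsFactors = FALSE
  )
  cond <- as.character(df$condition)
  if (is.null(conditions)) conditions <- unique(cond)
  bad <- setdiff(unique(cond), conditions)
  if (length(bad) > 0L)
    stop_traj("condition label(s) not in declared conditions: %s",
              paste(bad, collapse = ", "))
  out$condition <- factor(cond, levels = conditions)
  out
}

#' Cross-validate counts against metadata
#'
#' Hard error listing the symmetric difference when the sample universe of
#' the count matrix and the metadata disagree; otherwise returns the
#' metadata reordered to match the count matrix columns.
#'
#' @param counts Validated count matrix.
#' @param meta Sample table from [read_sample_table()].
#' @return `meta` reordered to the column order of `counts`.
#' @export
match_samples <- function(counts, meta) {
  a <- colnames(counts); b <- meta$sample_id
  only_counts <- setdiff(a, b); only_meta <- setdiff(b, a)
  if (length(only_counts) > 0L || length(only_meta) > 0L)
    stop_traj("sample ids differ between counts and metadata; only in counts: {%s}; only in metadata: {%s}",
              paste(only_counts, collapse = ", "),
              paste(only_meta, collapse = ", "))
  meta[match(a, b), , drop = FALSE]
}

#' Write a pipeline table to TSV
#'
#' Writes any of the pipeline's tabular outputs (data frames, or matrices
#' which are emitted with their row names as a leading id column) as
#' deterministic tab-separated UTF-8 with "." decimals and no quoting.
#'
#' @param obj Data frame or matrix.
#' @param path Output path.
#' @param id_column Name for the leading id column when `obj` is a matrix
#'   with row names. Default "id".
#' @return Invisibly, `path`.
#' @export
write_table <- function(obj, path, id_column = "id") {
  if (is.matrix(obj)) {
    df <- data.frame(rownames(obj), obj, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- id_column
    obj <- df
  }
  if (!is.data.frame(obj)) stop_traj("write_table expects a data frame or matrix")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_traj("output directory does not exist: %s", dir)
  ok <- tryCatch({
    utils::write.table(obj, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_traj("could not write table to %s", path)
  invisible(path)
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_counts()]: gene ids in the first column (`gene_id`),
#' sample ids in the header.
#'
#' @param counts Count matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path) {
  write_table(counts, path, id_column = "gene_id")
}
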