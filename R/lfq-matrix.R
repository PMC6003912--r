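#' Label-free quantification matrix
#'
#' `lfq_matrix()` bundles a proteins x samples abundance grid with the
#' per-protein identification records and per-sample metadata that the
#' discovery pipeline carries along. Missing intensities are stored as `NA`;
#' a raw-scale matrix never contains zeros (zeros are converted to missing at
#' parse time, see [read_protein_groups()]).
#'
#' @param values numeric matrix, proteins in rows, samples in columns.
#'   `NA` marks a missing (undetected) cell.
#' @param records tibble of per-protein identification metadata with columns
#'   `protein` (key, first accession of the group), `protein_ids` (list of
#'   accessions), `is_reverse`, `only_by_site`, `unique_razor_peptides` and
#'   optionally `sequence_coverage_pct`. One row per matrix row.
#' @param samples tibble of per-sample metadata; must contain `sample_id`
#'   matching the matrix column names. Typically the output of
#'   [read_sample_metadata()].
#' @param scale `"raw"` or `"log2"`.
#'
#' @return An object of class `lfq_matrix`.
#' @export
lfq_matrix <- function(values, records, samples, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values))
  if (nrow(values) != nrow(records)) {
    stop("`records` must have one row per matrix row (", nrow(values),
         " rows vs ", nrow(records), " records)", call. = FALSE)
  }
  if (ncol(values) != nrow(samples)) {
    stop("`samples` must have one row per matrix column (", ncol(values),
         " columns vs ", nrow(samples), " samples)", call. = FALSE)
  }
  if (!identical(colnames(values), samples$sample_id)) {
    stop("matrix column names must equal samples$sample_id, in order",
         call. = FALSE)
  }
  if (scale == "raw" && any(values[!is.na(values)] <= 0)) {
    stop("raw-scale matrix contains nonpositive present values", call. = FALSE)
  }
  rownames(values) <- records$protein
  structure(
    list(values = values, records = tibble::as_tibble(records),
         samples = tibble::as_tibble(samples), scale = scale),
    class = "lfq_matrix"
  )
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat(sprintf("<lfq_matrix> %d proteins x %d samples [%s scale], %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  if ("group" %in% names(x$samples)) {
    tab <- table(x$samples$group)
    cat("  samples:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.lfq_matrix <- function(x) dim(x$values)

#' Long-format view of an lfq_matrix
#'
#' @param x an [lfq_matrix()].
#' @param ... unused.
#' @return A tibble with one row per (protein, sample) cell: columns
#'   `protein`, `sample_id`, `intensity` (NA when missing) plus the sample
#'   metadata columns.
#' @method tidy lfq_matrix
#' @export
tidy.lfq_matrix <- function(x, ...) {
  long <- tibble::tibble(
    protein = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    intensity = as.vector(x$values)
  )
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' Attach (and reorder by) sample metadata
#'
#' Downstream stages take the metadata file, not the intensity-column order,
#' as the single source of truth for sample order. This reorders the matrix
#' columns to the metadata row order and attaches the metadata.
#'
#' @param x an [lfq_matrix()].
#' @param metadata a validated sample-metadata tibble
#'   (see [read_sample_metadata()]).
#' @return The reordered `lfq_matrix` with `metadata` as its `samples` slot.
#' @export
set_sample_metadata <- function(x, metadata) {
  stopifnot(inherits(x, "lfq_matrix"))
  metadata <- validate_sample_metadata(metadata)
  missing <- setdiff(metadata$sample_id, colnames(x$values))
  if (length(missing) > 0) {
    stop("metadata samples absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lfq_matrix(x$values[, metadata$sample_id, drop = FALSE], x$records,
             metadata, scale = x$scale)
}

#' Subset an lfq_matrix by protein row
#'
#' @param x an [lfq_matrix()].
#' @param keep logical or integer index over rows.
#' @return The row-subset `lfq_matrix` (row order preserved).
#' @export
filter_proteins <- function(x, keep) {
  lfq_matrix(x$values[keep, , drop = FALSE],
             x$records[keep, , drop = FALSE], x$samples, scale = x$scale)
}

# group labels (factor case/control) aligned to columns
sample_groups <- function(x) {
  stopifnot("group" %in% names(x$samples))
  factor(x$samples$group, levels = c("control", "case"))
}
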