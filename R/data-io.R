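#' Read a MaxQuant-style protein-groups table
#'
#' Parses the tab-separated `proteinGroups` dialect: one row per protein
#' group, identification metadata columns, and one intensity column per
#' analytical run identified by a shared prefix. Zero intensities are
#' converted to the explicit missing state at parse time, so that downstream
#' valid-value filtering and imputation see missingness rather than measured
#' zeros.
#'
#' A row is flagged as a decoy when the reverse column is marked *or* any of
#' its accessions carries the decoy prefix (MaxQuant emits both signals).
#'
#' @param path path to a tab-separated file with a header row.
#' @param decoy_prefix accession prefix marking reversed-database decoys.
#' @param intensity_prefix prefix of the per-run intensity columns; the
#'   remainder of each column name is taken as the run's sample id.
#' @param contaminant_prefix optional accession prefix for contaminant
#'   filtering; `NULL` (default) disables contaminant removal.
#' @param id_col,reverse_col,site_col,peptides_col,coverage_col column names
#'   of the MaxQuant dialect in use.
#' @return An [lfq_matrix()] on the raw scale whose `records` slot holds one
#'   `ProteinRecord` row per input row (column order preserved into sample
#'   order until [set_sample_metadata()] is applied).
#' @export
read_protein_groups <- function(path,
                                decoy_prefix = "REV__",
                                intensity_prefix = "Intensity ",
                                contaminant_prefix = NULL,
                                id_col = "Protein IDs",
                                reverse_col = "Reverse",
                                site_col = "Only identified by site",
                                peptides_col = "Unique + razor peptides",
                                coverage_col = "Sequence coverage [%]") {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in c(id_col, reverse_col, site_col, peptides_col)) {
    if (!col %in% names(raw)) {
      stop("protein-groups table is missing mandatory column '", col, "'",
           call. = FALSE)
    }
  }
  int_cols <- names(raw)[startsWith(names(raw), intensity_prefix)]
  if (length(int_cols) == 0) {
    stop("no intensity columns found with prefix '", intensity_prefix, "'",
         call. = FALSE)
  }
  sample_ids <- substring(int_cols, nchar(intensity_prefix) + 1L)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample columns: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }

  ids <- strsplit(raw[[id_col]], ";", fixed = TRUE)
  if (any(lengths(ids) == 0)) {
    stop("empty protein id field at row ", which(lengths(ids) == 0)[1],
         call. = FALSE)
  }
  marked <- function(col) !is.na(raw[[col]]) & trimws(raw[[col]]) != ""
  records <- tibble::tibble(
    protein = vapply(ids, `[`, character(1), 1L),
    protein_ids = ids,
    is_reverse = marked(reverse_col) |
      vapply(ids, function(v) any(startsWith(v, decoy_prefix)), logical(1)),
    only_by_site = marked(site_col),
    unique_razor_peptides = suppressWarnings(as.integer(raw[[peptides_col]])),
    is_contaminant = if (is.null(contaminant_prefix)) FALSE else
      vapply(ids, function(v) any(startsWith(v, contaminant_prefix)), logical(1))
  )
  if (anyNA(records$unique_razor_peptides) || any(records$unique_razor_peptides < 0)) {
    bad <- which(is.na(records$unique_razor_peptides) | records$unique_razor_peptides < 0)[1]
    stop("non-numeric or negative peptide count at row ", bad, call. = FALSE)
  }
  if (coverage_col %in% names(raw)) {
    records$sequence_coverage_pct <- suppressWarnings(as.numeric(raw[[coverage_col]]))
  }

  values <- matrix(NA_real_, nrow = nrow(raw), ncol = length(int_cols),
                   dimnames = list(records$protein, sample_ids))
  for (j in seq_along(int_cols)) {
    cell <- raw[[int_cols[j]]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell) & trimws(cell) != "" &
                   toupper(trimws(cell)) != "NA")
    if (length(bad) > 0) {
      stop(sprintf("non-numeric intensity '%s' at row %d, column '%s'",
                   cell[bad[1]], bad[1], int_cols[j]), call. = FALSE)
    }
    num[!is.na(num) & num == 0] <- NA_real_  # zero raw intensity == missing
    values[, j] <- num
  }
  lfq_matrix(values, records,
             tibble::tibble(sample_id = sample_ids), scale = "raw")
}

#' Read and validate a sample-metadata table
#'
#' @param path CSV or TSV with columns `sample_id`, `subject_id`, `group`
#'   (`case`/`control`), `pair_id`, `replicate`, `batch`.
#' @return A validated tibble (see [validate_sample_metadata()]).
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_delim(
    path,
    delim = if (grepl("\\.tsv$", path)) "\t" else ",",
    col_types = readr::cols(
      sample_id = readr::col_character(), subject_id = readr::col_character(),
      group = readr::col_character(), pair_id = readr::col_character(),
      replicate = readr::col_integer(), batch = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  validate_sample_metadata(meta)
}

#' Validate sample metadata invariants
#'
#' Checks column presence, group labels, uniqueness of
#' (subject_id, replicate), and that every matched pair id maps to exactly
#' one case and one control subject.
#'
#' @param meta a data frame of sample metadata.
#' @return `meta` as a tibble, invisibly unchanged apart from class.
#' @export
validate_sample_metadata <- function(meta) {
  required <- c("sample_id", "subject_id", "group", "pair_id", "replicate", "batch")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop("sample metadata is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_group <- setdiff(unique(meta$group), c("case", "control"))
  if (length(bad_group) > 0) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id values", call. = FALSE)
  }
  if (anyDuplicated(meta[, c("subject_id", "replicate")])) {
    stop("duplicate (subject_id, replicate) combinations", call. = FALSE)
  }
  subj <- dplyr::distinct(meta, .data$subject_id, .data$group, .data$pair_id)
  bad <- subj |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::summarise(n_case = sum(.data$group == "case"),
                     n_control = sum(.data$group == "control"),
                     .groups = "drop") |>
    dplyr::filter(.data$n_case != 1L | .data$n_control != 1L)
  if (nrow(bad) > 0) {
    stop("pair(s) without exactly one case and one control: ",
         paste(bad$pair_id, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(meta)
}

#' Read an SRM transition-results table
#'
#' Long-format CSV export of transition peak areas, one row per
#' (protein, peptide, fragment ion, sample, isotope label).
#' Light rows lacking a heavy partner are flagged in the `unpaired` column,
#' not dropped.
#'
#' @param path CSV with columns `protein`, `peptide`, `fragment`, `label`
#'   (`light`/`heavy`), `sample_id`, `batch`, `area`.
#' @return A validated tibble of class `srm_table`.
#' @export
read_srm_table <- function(path) {
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      protein = readr::col_character(), peptide = readr::col_character(),
      fragment = readr::col_character(), label = readr::col_character(),
      sample_id = readr::col_character(), batch = readr::col_character(),
      area = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  validate_srm_table(tbl)
}

#' Validate an SRM transition table
#'
#' @param tbl data frame with the `srm_table` columns.
#' @return The validated tibble with class `srm_table` prepended and a
#'   logical `unpaired` column marking light rows without a heavy partner.
#' @export
validate_srm_table <- function(tbl) {
  required <- c("protein", "peptide", "fragment", "label", "sample_id", "batch", "area")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("SRM table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_label <- setdiff(unique(tbl$label), c("light", "heavy"))
  if (length(bad_label) > 0) {
    stop("unknown isotope label(s): ", paste(bad_label, collapse = ", "),
         call. = FALSE)
  }
  if (any(tbl$area < 0, na.rm = TRUE)) {
    stop("negative peak area at row ", which(tbl$area < 0)[1], call. = FALSE)
  }
  key <- c("protein", "peptide", "fragment", "sample_id", "label")
  if (anyDuplicated(tbl[, key])) {
    stop("duplicate (protein, peptide, fragment, sample, label) rows",
         call. = FALSE)
  }
  tbl <- tibble::as_tibble(tbl)
  heavy <- dplyr::filter(tbl, .data$label == "heavy")
  tbl$unpaired <- tbl$label == "light" &
    !paste(tbl$protein, tbl$peptide, tbl$fragment, tbl$sample_id) %in%
      paste(heavy$protein, heavy$peptide, heavy$fragment, heavy$sample_id)
  class(tbl) <- c("srm_table", class(tbl))
  tbl
}

#' Write / read a differential-abundance results table
#'
#' Columns mirror the discovery-phase reporting layout: protein, log2 fold
#' change, test statistic, p-value, FDR. FDR values below the permutation
#' resolution are rendered as `"<1e-04"` (an FDR printed as 0 means a value
#' below 1e-4, not a true zero).
#'
#' @param results a `diff_table` tibble from [differential_table()].
#' @param path output CSV path.
#' @param fdr_resolution values strictly below this are rendered as below
#'   resolution.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(results, path, fdr_resolution = 1e-4) {
  stopifnot(nrow(results) > 0)
  out <- results |>
    dplyr::select("protein", "log2_fc", "d", "p_value", "fdr") |>
    dplyr::mutate(fdr = ifelse(.data$fdr < fdr_resolution,
                               paste0("<", format(fdr_resolution)),
                               format(.data$fdr, digits = 6, scientific = FALSE)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_diff_table
#' @details `read_diff_table()` reads the file back; sub-resolution FDR
#'   strings are parsed as `fdr_resolution / 2` with `fdr_censored = TRUE`.
#' @export
read_diff_table <- function(path, fdr_resolution = 1e-4) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    protein = readr::col_character(), log2_fc = readr::col_double(),
    d = readr::col_double(), p_value = readr::col_double(),
    fdr = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  censored <- startsWith(tbl$fdr, "<")
  tbl$fdr_censored <- censored
  tbl$fdr <- ifelse(censored, fdr_resolution / 2, suppressWarnings(as.numeric(tbl$fdr)))
  tbl
}

#' Write a panel-selection report as JSON
#'
#' @param panel a `panel_fit` object from [select_panel()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_panel_report <- function(panel, path) {
  stopifnot(inherits(panel, "panel_fit"))
  report <- list(
    panel = panel$panel,
    candidates = panel$candidates,
    frequencies = panel$frequencies,
    auroc_single = panel$auroc_single,
    auroc_panel = panel$auroc_panel,
    auroc_panel_apparent = panel$auroc_panel_apparent,
    comparison_p = panel$comparison_p,
    trace = panel$trace
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
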