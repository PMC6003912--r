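#' Discovery-phase preprocessing configuration
#'
#' Houses the constants of the filtering / transformation / imputation chain:
#' proteins must be identified by more than one unique + razor peptide, must
#' carry valid (non-missing) values in at least half of the analytical runs,
#' and remaining missing values are imputed from a normal distribution
#' downshifted by 1.8 column standard deviations and shrunk to width 0.3 —
#' the standard left-censored (MNAR) convention for label-free data.
#'
#' @param min_unique_razor_peptides minimum unique + razor peptide count
#'   (default 2, i.e. "more than one peptide").
#' @param min_valid_fraction minimum fraction of present values per protein
#'   across analytical runs; the boundary is inclusive ("at least 50%").
#' @param imputation_width imputed spread as a multiple of the column sd.
#' @param imputation_downshift imputed mean shift below the column mean, in
#'   column sds.
#' @param imputation_scope `"per_sample"` (column-wise moments, default) or
#'   `"global"` (whole-matrix moments) imputation.
#' @param seed integer seed for the imputation draws.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(min_unique_razor_peptides = 2L,
                              min_valid_fraction = 0.5,
                              imputation_width = 0.3,
                              imputation_downshift = 1.8,
                              imputation_scope = c("per_sample", "global"),
                              seed = 1L) {
  stopifnot(min_valid_fraction > 0, min_valid_fraction <= 1,
            imputation_width > 0, imputation_downshift >= 0)
  structure(list(
    min_unique_razor_peptides = as.integer(min_unique_razor_peptides),
    min_valid_fraction = min_valid_fraction,
    imputation_width = imputation_width,
    imputation_downshift = imputation_downshift,
    imputation_scope = match.arg(imputation_scope),
    seed = as.integer(seed)
  ), class = "preprocess_config")
}

#' Filter out unreliable protein identifications
#'
#' Removes reverse (decoy) hits, proteins only identified by a modification
#' site, proteins identified by fewer unique + razor peptides than the
#' configured minimum, and (optionally flagged) contaminants. Row order is
#' preserved. The per-rule removal counts are attached as the
#' `"filter_report"` attribute; a row failing several rules is counted under
#' each rule it fails, while `removed_total` counts unique rows.
#'
#' @param x an [lfq_matrix()] whose `records` are aligned to its rows.
#' @param cfg a [preprocess_config()].
#' @return The filtered `lfq_matrix` with a `filter_report` attribute.
#' @export
filter_identifications <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(x, "lfq_matrix"))
  r <- x$records
  fail_reverse <- r$is_reverse
  fail_site <- r$only_by_site
  fail_peptides <- r$unique_razor_peptides < cfg$min_unique_razor_peptides
  fail_contaminant <- if ("is_contaminant" %in% names(r)) r$is_contaminant else FALSE
  drop <- fail_reverse | fail_site | fail_peptides | fail_contaminant
  out <- filter_proteins(x, !drop)
  attr(out, "filter_report") <- tibble::tibble(
    rule = c("reverse", "only_by_site", "min_peptides", "contaminant",
             "removed_total", "retained"),
    n = c(sum(fail_reverse), sum(fail_site), sum(fail_peptides),
          sum(fail_contaminant), sum(drop), sum(!drop))
  )
  out
}

#' Log2-transform a raw intensity matrix
#'
#' @param x an [lfq_matrix()] on the raw scale; all present values must be
#'   positive. Missing cells stay missing.
#' @return The matrix on the log2 scale.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (x$scale != "raw") stop("matrix is already log2-transformed", call. = FALSE)
  v <- x$values
  if (any(v[!is.na(v)] <= 0)) {
    stop("nonpositive present intensity; cannot log2-transform", call. = FALSE)
  }
  x$values <- log2(v)
  x$scale <- "log2"
  x
}

#' Filter proteins on the fraction of valid values
#'
#' Keeps proteins whose fraction of present (valid) cells over all analytical
#' runs is at least `cfg$min_valid_fraction`. Computed before replicate
#' averaging, i.e. over runs, not subjects.
#'
#' @inheritParams filter_identifications
#' @return The filtered `lfq_matrix`; removal count in the `filter_report`
#'   attribute.
#' @export
filter_valid_fraction <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(x, "lfq_matrix"), x$scale == "log2")
  frac <- rowMeans(!is.na(x$values))
  keep <- frac >= cfg$min_valid_fraction
  out <- filter_proteins(x, keep)
  attr(out, "filter_report") <- tibble::tibble(
    rule = c("below_valid_fraction", "retained"),
    n = c(sum(!keep), sum(keep))
  )
  out
}

#' Impute missing values from a downshifted normal distribution
#'
#' Each missing cell in scope unit u (a sample column under the default
#' per-sample scope) is replaced by a draw from
#' Normal(mean_u - downshift * sd_u, (width * sd_u)^2), with mean_u and sd_u
#' computed from the present values of u. Present cells are never touched;
#' the draws are seeded and reproducible.
#'
#' @inheritParams filter_identifications
#' @param seed overrides `cfg$seed` when given.
#' @return The fully imputed `lfq_matrix` with a logical attribute
#'   `"imputed_mask"` marking the filled cells.
#' @export
impute_downshifted_normal <- function(x, cfg = preprocess_config(), seed = NULL) {
  stopifnot(inherits(x, "lfq_matrix"), x$scale == "log2")
  v <- x$values
  mask <- is.na(v)
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  if (any(mask)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    if (cfg$imputation_scope == "per_sample") {
      for (j in seq_len(ncol(v))) {
        nj <- sum(!mask[, j])
        if (nj < 2) {
          stop("sample '", colnames(v)[j],
               "' has fewer than 2 present values; cannot impute", call. = FALSE)
        }
        if (!any(mask[, j])) next
        m <- mean(v[, j], na.rm = TRUE)
        s <- stats::sd(v[, j], na.rm = TRUE)
        v[mask[, j], j] <- stats::rnorm(sum(mask[, j]),
                                        mean = m - cfg$imputation_downshift * s,
                                        sd = cfg$imputation_width * s)
      }
    } else {
      if (sum(!mask) < 2) stop("fewer than 2 present values overall", call. = FALSE)
      m <- mean(v, na.rm = TRUE)
      s <- stats::sd(as.vector(v), na.rm = TRUE)
      v[mask] <- stats::rnorm(sum(mask),
                              mean = m - cfg$imputation_downshift * s,
                              sd = cfg$imputation_width * s)
    }
  }
  x$values <- v
  attr(x, "imputed_mask") <- mask
  x
}

#' Average technical replicates into subject-level columns
#'
#' Collapses the replicate runs of each subject to their arithmetic mean,
#' producing one column per subject. Requires a fully imputed (or at least
#' mean-safe) matrix; means are taken over present values.
#'
#' @param x an [lfq_matrix()] with `subject_id` in its sample metadata.
#' @return A subject-level `lfq_matrix`; its `samples` slot has one row per
#'   subject (replicate column dropped, `sample_id` = subject id).
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "lfq_matrix"), x$scale == "log2",
            "subject_id" %in% names(x$samples))
  subjects <- unique(x$samples$subject_id)
  v <- matrix(NA_real_, nrow = nrow(x$values), ncol = length(subjects),
              dimnames = list(rownames(x$values), subjects))
  for (k in seq_along(subjects)) {
    cols <- which(x$samples$subject_id == subjects[k])
    if (length(cols) == 0) stop("subject without columns", call. = FALSE)
    v[, k] <- rowMeans(x$values[, cols, drop = FALSE], na.rm = TRUE)
  }
  v[is.nan(v)] <- NA_real_
  meta <- x$samples |>
    dplyr::distinct(.data$subject_id, .data$group, .data$pair_id) |>
    dplyr::slice(match(subjects, .data$subject_id)) |>
    dplyr::mutate(sample_id = .data$subject_id, .before = 1)
  lfq_matrix(v, x$records, meta, scale = "log2")
}

#' Run the full discovery-phase preprocessing chain
#'
#' Applies, in this fixed order: identification filtering, log2
#' transformation, valid-value filtering, downshifted-normal imputation,
#' replicate averaging. The order matters (imputing before averaging is not
#' the same as after) and is enforced here.
#'
#' @param x a raw-scale [lfq_matrix()] with sample metadata attached
#'   (see [set_sample_metadata()]).
#' @param cfg a [preprocess_config()].
#' @return The subject-level analysis `lfq_matrix`; the combined per-stage
#'   filter report is in the `"filter_report"` attribute.
#' @export
preprocess <- function(x, cfg = preprocess_config()) {
  n_in <- nrow(x$values)
  x1 <- filter_identifications(x, cfg)
  rep1 <- attr(x1, "filter_report")
  x2 <- log2_transform(x1)
  x3 <- filter_valid_fraction(x2, cfg)
  rep2 <- attr(x3, "filter_report")
  x4 <- impute_downshifted_normal(x3, cfg)
  out <- average_replicates(x4)
  attr(out, "filter_report") <- dplyr::bind_rows(
    tibble::tibble(rule = "input_rows", n = n_in),
    dplyr::mutate(rep1, stage = "identifications"),
    dplyr::mutate(rep2, stage = "valid_fraction")
  )
  out
}

# save/restore the global RNG state so seeded helpers do not perturb
# the caller's random stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
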