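#' SRM verification configuration
#'
#' @param housekeeping_protein,housekeeping_peptide the spiked housekeeping
#'   reference used for per-sample normalization (default: the TNFDNDIALVR
#'   peptide of complement C1s subcomponent, P09871).
#' @param peptide_include_list named list mapping a protein to the subset of
#'   its peptides admitted to statistics (the in-silico counterpart of
#'   manual interference curation; default restricts fibulin-1 proteoform C
#'   to DLLLTVK).
#' @param ci_level confidence level of the ratio interval (default 0.99).
#' @param adjust_method multiplicity adjustment across target proteins.
#' @param exclude_from_family proteins measured but kept out of the
#'   adjustment family (housekeeping references and the apolipoprotein B-100
#'   risk-factor control, by default).
#' @return A list of class `srm_config`.
#' @export
srm_config <- function(housekeeping_protein = "P09871",
                       housekeeping_peptide = "TNFDNDIALVR",
                       peptide_include_list = list("P23142-4" = "DLLLTVK"),
                       ci_level = 0.99,
                       adjust_method = "BH",
                       exclude_from_family = c("P09871", "P04217", "P04114")) {
  stopifnot(ci_level > 0, ci_level < 1)
  structure(list(
    housekeeping_protein = housekeeping_protein,
    housekeeping_peptide = housekeeping_peptide,
    peptide_include_list = peptide_include_list,
    ci_level = ci_level, adjust_method = match.arg(adjust_method, "BH"),
    exclude_from_family = exclude_from_family
  ), class = "srm_config")
}

#' Light/heavy log2 transition ratios
#'
#' Pairs each light transition row with its heavy (spiked standard) partner
#' and returns log2(light area / heavy area). Rows lacking a partner, or
#' with a zero/missing area on either channel, are dropped and counted in
#' the `"dropped"` attribute rather than raising an error.
#'
#' @param table an `srm_table` (see [read_srm_table()]).
#' @return A tibble (`protein`, `peptide`, `fragment`, `sample_id`, `batch`,
#'   `log2_ratio`).
#' @export
light_heavy_log_ratio <- function(table) {
  wide <- table |>
    dplyr::select("protein", "peptide", "fragment", "sample_id", "batch",
                  "label", "area") |>
    tidyr::pivot_wider(names_from = "label", values_from = "area")
  if (!"heavy" %in% names(wide)) wide$heavy <- NA_real_
  if (!"light" %in% names(wide)) wide$light <- NA_real_
  usable <- !is.na(wide$light) & !is.na(wide$heavy) & wide$heavy > 0 & wide$light > 0
  out <- wide |>
    dplyr::filter(usable) |>
    dplyr::mutate(log2_ratio = log2(.data$light / .data$heavy)) |>
    dplyr::select(-"light", -"heavy")
  attr(out, "dropped") <- sum(!usable)
  out
}

#' Normalize transition ratios to the housekeeping peptide
#'
#' Subtracts, per sample, the median housekeeping-peptide log2 ratio of that
#' sample from every analyte log2 ratio, removing sample-level (e.g. batch
#' drift or loading) offsets. Idempotent up to the housekeeping peptide's
#' own measurement noise only in the sense that the housekeeping median is
#' exactly zero after the first application.
#'
#' @param ratios tibble from [light_heavy_log_ratio()].
#' @param cfg an [srm_config()].
#' @return The normalized ratios tibble.
#' @export
normalize_to_housekeeping <- function(ratios, cfg = srm_config()) {
  hk <- ratios |>
    dplyr::filter(.data$protein == cfg$housekeeping_protein,
                  .data$peptide == cfg$housekeeping_peptide) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(hk_median = stats::median(.data$log2_ratio), .groups = "drop")
  missing <- setdiff(unique(ratios$sample_id), hk$sample_id)
  if (length(missing) > 0) {
    stop("sample(s) missing the housekeeping peptide: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ratios |>
    dplyr::left_join(hk, by = "sample_id") |>
    dplyr::mutate(log2_ratio = .data$log2_ratio - .data$hk_median) |>
    dplyr::select(-"hk_median")
}

#' Tukey median polish of a transitions x samples matrix
#'
#' Iteratively removes row and column medians until the maximum absolute
#' change is below `eps` or `maxiter` sweeps, decomposing the matrix into
#' overall + row effects + column effects + residuals (exact on present
#' cells). The protein-level per-sample summary is overall + column effect.
#'
#' @param mat numeric matrix of log2 ratios, transitions in rows, samples in
#'   columns; `NA` cells allowed.
#' @param eps,maxiter convergence tolerance and sweep cap.
#' @return A list with `overall`, `row_effects`, `col_effects`, `residuals`
#'   and `sample_summary` (= overall + col_effects).
#' @export
median_polish <- function(mat, eps = 1e-6, maxiter = 50L) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1, ncol(mat) >= 1)
  if (any(colSums(!is.na(mat)) == 0)) {
    stop("all-missing sample column in median polish input", call. = FALSE)
  }
  mp <- stats::medpolish(mat, eps = eps, maxiter = maxiter, na.rm = TRUE,
                         trace.iter = FALSE)
  list(overall = mp$overall, row_effects = mp$row, col_effects = mp$col,
       residuals = mp$residuals,
       sample_summary = mp$overall + mp$col)
}

#' Protein-level per-sample SRM summaries
#'
#' Applies the peptide include-list, then median-polishes each protein's
#' (transition x sample) grid of normalized log2 ratios into one summary
#' value per sample.
#'
#' @param ratios normalized ratios tibble (see
#'   [normalize_to_housekeeping()]).
#' @param cfg an [srm_config()].
#' @return A tibble (`protein`, `sample_id`, `log2_summary`,
#'   `n_transitions_used`).
#' @export
summarize_srm_proteins <- function(ratios, cfg = srm_config()) {
  res <- ratios |>
    dplyr::group_by(.data$protein) |>
    dplyr::group_map(function(df, key) {
      prot <- key$protein[[1]]
      inc <- cfg$peptide_include_list[[prot]]
      if (!is.null(inc)) df <- dplyr::filter(df, .data$peptide %in% inc)
      if (nrow(df) == 0) return(NULL)
      df$transition <- paste(df$peptide, df$fragment, sep = "|")
      mat <- df |>
        dplyr::select("transition", "sample_id", "log2_ratio") |>
        tidyr::pivot_wider(names_from = "sample_id", values_from = "log2_ratio")
      m <- as.matrix(mat[, -1, drop = FALSE])
      rownames(m) <- mat$transition
      mp <- median_polish(m)
      tibble::tibble(protein = prot, sample_id = colnames(m),
                     log2_summary = unname(mp$sample_summary),
                     n_transitions_used = nrow(m))
    }) |>
    dplyr::bind_rows()
  res
}

#' Case/control group comparison of SRM protein summaries
#'
#' Per protein, an equal-variance linear model of the per-sample log2
#' summaries on group membership: the case-minus-control coefficient is the
#' protein's log2 case/control ratio, with a Wald confidence interval at
#' `ci_level` and a two-sided p-value. P-values are Benjamini-Hochberg
#' adjusted across the target-protein family (housekeeping and risk-factor
#' controls excluded), and results are sorted by adjusted p.
#'
#' @param summaries tibble from [summarize_srm_proteins()].
#' @param metadata tibble with `sample_id` (here: one SRM run per subject)
#'   and `group`.
#' @param cfg an [srm_config()].
#' @return A tibble of class `srm_result` (`protein`, `log2_ratio`, `ratio`,
#'   `ci_low`, `ci_high` on the ratio scale, `p_value`, `p_adjusted`,
#'   `n_transitions_used`, `in_family`); the per-sample summaries are kept
#'   in the `"sample_summaries"` attribute for plotting.
#' @export
srm_group_compare <- function(summaries, metadata, cfg = srm_config()) {
  dat <- summaries |>
    dplyr::inner_join(dplyr::select(metadata, "sample_id", "group"),
                      by = "sample_id")
  res <- dat |>
    dplyr::group_by(.data$protein) |>
    dplyr::group_map(function(df, key) {
      tab <- table(df$group)
      if (length(tab) < 2 || any(tab < 2)) {
        warning("protein ", key$protein[[1]],
                " has fewer than 2 subjects per group; excluded")
        return(NULL)
      }
      is_case <- as.integer(df$group == "case")
      fit <- stats::lm(df$log2_summary ~ is_case)
      est <- stats::coef(fit)[["is_case"]]
      # noise-free (zero-residual) fits are legitimate here; summary.lm warns
      sm <- suppressWarnings(summary(fit))
      se <- sm$coefficients["is_case", "Std. Error"]
      dfree <- fit$df.residual
      tq <- stats::qt((1 + cfg$ci_level) / 2, dfree)
      pval <- sm$coefficients["is_case", "Pr(>|t|)"]
      tibble::tibble(protein = key$protein[[1]], log2_ratio = est,
                     ratio = 2^est,
                     ci_low = 2^(est - tq * se), ci_high = 2^(est + tq * se),
                     p_value = pval,
                     n_transitions_used = df$n_transitions_used[1])
    }) |>
    dplyr::bind_rows()
  res$in_family <- !(res$protein %in% cfg$exclude_from_family)
  res$p_adjusted <- NA_real_
  res$p_adjusted[res$in_family] <-
    stats::p.adjust(res$p_value[res$in_family], method = cfg$adjust_method)
  res <- dplyr::arrange(res, !res$in_family, .data$p_adjusted, .data$p_value)
  attr(res, "sample_summaries") <- dat
  class(res) <- c("srm_result", class(res))
  res
}

#' Run the whole SRM verification chain
#'
#' Light/heavy ratios, housekeeping normalization, include-list filtering,
#' median-polish summarization and group comparison with BH adjustment.
#'
#' @param table an `srm_table`.
#' @param metadata sample metadata with `sample_id` and `group`.
#' @param cfg an [srm_config()].
#' @return An `srm_result` tibble (see [srm_group_compare()]).
#' @export
srm_verify <- function(table, metadata, cfg = srm_config()) {
  ratios <- light_heavy_log_ratio(table)
  normed <- normalize_to_housekeeping(ratios, cfg)
  summaries <- summarize_srm_proteins(normed, cfg)
  srm_group_compare(summaries, metadata, cfg)
}
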