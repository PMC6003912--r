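#' Deterministic per-stage child seeds
#'
#' Derives a stage-specific seed from the global run seed and the stage
#' name, so each stage's random stream is reproducible independently of
#' execution order. Always below 2^31.
#'
#' @param seed integer global seed.
#' @param stage stage name.
#' @return An integer seed.
#' @export
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435.0) %% 2147483647)
}

#' Run the discovery phase end to end
#'
#' Fixed order: ingestion (or in-memory inputs), preprocessing chain,
#' reproducibility-optimized differential testing, stability-based panel
#' selection. A manifest records seeds, filter counts and thresholds.
#'
#' @param protein_groups path to a protein-groups TSV, or a raw-scale
#'   [lfq_matrix()].
#' @param metadata path to a sample-metadata CSV, or a metadata tibble.
#' @param preprocess_cfg,rots,panel_cfg stage configurations; stage seeds
#'   are overridden by children of `seed`.
#' @param seed global run seed.
#' @param out_dir optional output directory; when given, the differential
#'   table (CSV), panel report (JSON) and manifest (JSON) are written there.
#' @return A list of class `discovery_run`: `diff` (diff_table), `panel`
#'   (panel_fit or `NULL` when no protein was ever selected), `matrix` (the
#'   preprocessed subject-level matrix), `manifest`.
#' @export
run_discovery <- function(protein_groups, metadata,
                          preprocess_cfg = preprocess_config(),
                          rots = rots_params(),
                          panel_cfg = panel_config(),
                          seed = 1L, out_dir = NULL) {
  mat <- if (inherits(protein_groups, "lfq_matrix")) protein_groups
    else read_protein_groups(protein_groups)
  meta <- if (is.data.frame(metadata)) validate_sample_metadata(metadata)
    else read_sample_metadata(metadata)
  mat <- set_sample_metadata(mat, meta)

  preprocess_cfg$seed <- child_seed(seed, "impute")
  rots$seed <- child_seed(seed, "diffabund")
  panel_cfg$seed <- child_seed(seed, "panel")

  sub <- preprocess(mat, preprocess_cfg)
  report <- attr(sub, "filter_report")
  diff <- differential_table(sub, rots)

  panel <- NULL
  freq <- lasso_stability(sub, panel_cfg)
  if (any(freq$n_selected > 0)) {
    panel <- select_panel(freq, sub, panel_cfg, diff = diff)
  }

  manifest <- list(
    seed = seed,
    stage_seeds = list(impute = preprocess_cfg$seed, diffabund = rots$seed,
                       panel = panel_cfg$seed),
    n_input_rows = nrow(mat$values), n_runs = ncol(mat$values),
    n_subjects = ncol(sub$values), n_retained = nrow(sub$values),
    filter_report = report,
    rots_fit = attr(diff, "rots_fit"),
    thresholds = list(
      min_unique_razor_peptides = preprocess_cfg$min_unique_razor_peptides,
      min_valid_fraction = preprocess_cfg$min_valid_fraction,
      prescreen_p = panel_cfg$prescreen_p_threshold,
      improvement_p = panel_cfg$improvement_p_threshold),
    panel_found = !is.null(panel)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_diff_table(diff, file.path(out_dir, "differential_abundance.csv"))
    if (!is.null(panel)) {
      write_panel_report(panel, file.path(out_dir, "panel.json"))
    }
    manifest_out <- manifest
    manifest_out$filter_report <- as.list(stats::setNames(report$n, report$rule))
    jsonlite::write_json(manifest_out, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(diff = diff, panel = panel, matrix = sub, manifest = manifest),
            class = "discovery_run")
}

#' Run the SRM verification phase
#'
#' @param srm path to an SRM transition CSV, or an `srm_table`.
#' @param metadata path to a metadata CSV, or a tibble with `sample_id` and
#'   `group`.
#' @param cfg an [srm_config()].
#' @param out_dir optional output directory for the results CSV and the
#'   per-sample summary CSV.
#' @return An `srm_result` tibble.
#' @export
run_verification <- function(srm, metadata, cfg = srm_config(),
                             out_dir = NULL) {
  tbl <- if (inherits(srm, "srm_table")) srm else read_srm_table(srm)
  meta <- if (is.data.frame(metadata)) metadata else read_sample_metadata(metadata)
  res <- srm_verify(tbl, meta, cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(as.data.frame(res), file.path(out_dir, "srm_results.csv"),
                     progress = FALSE)
    readr::write_csv(attr(res, "sample_summaries"),
                     file.path(out_dir, "srm_sample_summaries.csv"),
                     progress = FALSE)
  }
  res
}
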