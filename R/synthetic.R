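#' Discovery-phase simulation parameters
#'
#' The defaults emulate the matched case/control discovery design: 43
#' matched pairs analyzed in quadruplicate (344 runs), ~300 protein groups,
#' seven small planted log2 effects matching the magnitudes reported for
#' the differentially abundant serum proteins (-0.35 to +0.40), and an
#' intensity-dependent (left-censored, MNAR) missingness mechanism: a cell
#' is observed with probability 1 - pnorm((midpoint - value) / slope), so
#' lower-abundance measurements go missing more often.
#'
#' @param n_pairs matched case/control pairs.
#' @param n_replicates technical replicates per subject.
#' @param n_proteins quantified (non-decoy, multi-peptide) proteins.
#' @param baseline_mean,baseline_sd per-protein baseline log2 abundance
#'   distribution.
#' @param replicate_sd technical (replicate-to-replicate) log2 noise.
#' @param biological_sd between-subject log2 noise.
#' @param planted_effects named numeric vector: planted case-minus-control
#'   log2 differences by protein index.
#' @param missing_midpoint,missing_slope probit MNAR detection parameters on
#'   the log2 scale.
#' @param decoy_fraction,single_peptide_fraction fractions (of `n_proteins`)
#'   of additional reversed-decoy and single-peptide rows injected so that
#'   identification filtering is exercised.
#' @param seed integer seed.
#' @return A list of class `discovery_sim_params`.
#' @export
discovery_sim_params <- function(n_pairs = 43L, n_replicates = 4L,
                                 n_proteins = 300L,
                                 baseline_mean = 24, baseline_sd = 2,
                                 replicate_sd = 0.15, biological_sd = 0.5,
                                 planted_effects = stats::setNames(
                                   c(-0.35, -0.32, -0.27, -0.19, -0.13, 0.22, 0.40),
                                   as.character(1:7)),
                                 missing_midpoint = 20, missing_slope = 1,
                                 decoy_fraction = 0.05,
                                 single_peptide_fraction = 0.05,
                                 seed = 1L) {
  stopifnot(n_pairs >= 1, n_replicates >= 1, n_proteins >= 1,
            replicate_sd >= 0, biological_sd >= 0, missing_slope > 0,
            all(is.finite(planted_effects)),
            all(as.integer(names(planted_effects)) <= n_proteins))
  structure(list(
    n_pairs = as.integer(n_pairs), n_replicates = as.integer(n_replicates),
    n_proteins = as.integer(n_proteins),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    replicate_sd = replicate_sd, biological_sd = biological_sd,
    planted_effects = planted_effects,
    missing_midpoint = missing_midpoint, missing_slope = missing_slope,
    decoy_fraction = decoy_fraction,
    single_peptide_fraction = single_peptide_fraction,
    seed = as.integer(seed)
  ), class = "discovery_sim_params")
}

#' Simulate a discovery-phase protein-groups data set with ground truth
#'
#' Per protein p and subject s, the true log2 value is
#' baseline_p + delta_p * is_case_s + biological noise; each replicate run
#' adds technical noise; a cell is observed with probability
#' 1 - pnorm((midpoint - value) / slope); raw intensity is 2^value.
#' Reversed-decoy and single-peptide rows are appended so identification
#' filters have work to do.
#'
#' @param params a [discovery_sim_params()].
#' @return A list: `matrix` (raw-scale [lfq_matrix()] with records and
#'   metadata attached), `metadata` (the sample tibble), and `truth` with
#'   the planted deltas (full-length vector), the subject-level true log2
#'   matrix, the missing mask and the injected-row bookkeeping.
#' @export
simulate_discovery <- function(params = discovery_sim_params()) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(params$seed)
  np <- params$n_proteins; ns <- 2L * params$n_pairs
  nrun <- ns * params$n_replicates

  subj <- sprintf("S%03d", seq_len(ns))
  group <- rep(c("case", "control"), params$n_pairs)
  pair <- rep(sprintf("P%02d", seq_len(params$n_pairs)), each = 2)
  metadata <- tibble::tibble(
    sample_id = paste0(rep(subj, each = params$n_replicates), "_r",
                       rep(seq_len(params$n_replicates), ns)),
    subject_id = rep(subj, each = params$n_replicates),
    group = rep(group, each = params$n_replicates),
    pair_id = rep(pair, each = params$n_replicates),
    replicate = rep(seq_len(params$n_replicates), ns),
    batch = paste0("B", rep(seq_len(params$n_replicates), ns))
  )

  deltas <- numeric(np)
  idx <- as.integer(names(params$planted_effects))
  deltas[idx] <- unname(params$planted_effects)
  prot <- sprintf("PROT%04d", seq_len(np))
  names(deltas) <- prot

  baseline <- stats::rnorm(np, params$baseline_mean, params$baseline_sd)
  true_subj <- baseline +
    outer(deltas, as.numeric(group == "case")) +
    matrix(stats::rnorm(np * ns, 0, params$biological_sd), np, ns)
  dimnames(true_subj) <- list(prot, subj)

  run_vals <- true_subj[, rep(seq_len(ns), each = params$n_replicates)] +
    matrix(stats::rnorm(np * nrun, 0, params$replicate_sd), np, nrun)
  colnames(run_vals) <- metadata$sample_id
  p_obs <- 1 - stats::pnorm((params$missing_midpoint - run_vals) /
                              params$missing_slope)
  observed <- matrix(stats::runif(np * nrun) < p_obs, np, nrun)
  values <- 2^run_vals
  values[!observed] <- NA_real_

  n_decoy <- round(params$decoy_fraction * np)
  n_single <- round(params$single_peptide_fraction * np)
  extra <- n_decoy + n_single
  if (extra > 0) {
    ev <- 2^(params$baseline_mean - 2 +
               matrix(stats::rnorm(extra * nrun, 0, 1), extra, nrun))
    keep_obs <- matrix(stats::runif(extra * nrun) < 0.8, extra, nrun)
    ev[!keep_obs] <- NA_real_
    extra_names <- c(sprintf("REV__X%03d", seq_len(n_decoy)),
                     sprintf("SINGLE%03d", seq_len(n_single)))
    rownames(ev) <- extra_names
    values <- rbind(values, ev)
  }

  records <- tibble::tibble(
    protein = rownames(values),
    protein_ids = as.list(rownames(values)),
    is_reverse = c(rep(FALSE, np), rep(TRUE, n_decoy), rep(FALSE, n_single)),
    only_by_site = FALSE,
    unique_razor_peptides = c(2L + stats::rpois(np, 5),
                              rep(2L, n_decoy), rep(1L, n_single)),
    is_contaminant = FALSE,
    sequence_coverage_pct = round(stats::runif(np + extra, 5, 80), 1)
  )

  mat <- lfq_matrix(values, records, metadata, scale = "raw")
  list(matrix = mat, metadata = metadata,
       truth = list(deltas = deltas, true_log2_subject = true_subj,
                    missing_mask = !observed,
                    baseline = stats::setNames(baseline, prot),
                    n_decoy = n_decoy, n_single_peptide = n_single))
}

# SRM assay layout: 10 proteins / 23 proteotypic peptides (plus spiked iRT
# standards, which carry no light channel and are not simulated)
srm_assay_peptides <- function() {
  tibble::tribble(
    ~protein, ~peptide,
    "P04114", "EYSGTIASEANTYLNSK",
    "P04114", "ENFAGEATLQR",
    "P04114", "EVGTVLSQVYSK",
    "P02656", "DALSSVQESQVAQQAR",
    "P02656", "GWVTDGFSSLK",
    "P04217", "NGVAQEPVHLDSPAIK",
    "P04217", "SGLSTGWTQLSK",
    "P09871", "IIGGSDADIK",
    "P09871", "TNFDNDIALVR",
    "P09871", "GDSGGAFAVQDPNDK",
    "P23142-4", "DLLLTVK",
    "P23142-4", "HGTVSSFVAK",
    "P02649", "LGPLVEQGR",
    "P02649", "LEEQAQQIR",
    "P06396", "AGALNSNDAFVLK",
    "P06396", "TPSAAYLWVGTGASEAEK",
    "P08253", "IIGYTPDLDPETVDDAFAR",
    "P08253", "AFQVWSDVTPLR",
    "P55290", "DVGKVVDSDRPER",
    "P55290", "INENTGSVSVTR",
    "Q96KN2", "EWVAIESDSVQPVPR",
    "Q96KN2", "FRQELFR",
    "Q96KN2", "ALEQDLPVNIK"
  )
}

#' SRM simulation parameters
#'
#' Defaults reproduce the targeted assay layout (10 proteins, 23
#' proteotypic peptides, 3 transitions each) on the same 43-pair design,
#' with one SRM run per subject, a housekeeping peptide tracking batch
#' drift at a planted case/control ratio of 1, and a planted fibulin-1C
#' ratio of 0.85.
#'
#' @param n_pairs matched pairs (one undepleted serum run per subject).
#' @param transitions_per_peptide fragment ions monitored per peptide.
#' @param heavy_area mean heavy-standard peak area (spike level).
#' @param planted_ratios named case/control ratio per protein; proteins not
#'   named get ratio 1.
#' @param base_log2_ratio mean light/heavy log2 ratio of an analyte in
#'   controls.
#' @param biological_sd between-subject sd of the analyte log2 ratio.
#' @param housekeeping_sd between-subject sd of the housekeeping protein's
#'   log2 ratio; small by design, since housekeeping references are chosen
#'   for their consistency and their noise propagates through normalization
#'   into every analyte.
#' @param noise_sd transition-level measurement noise sd (log2).
#' @param batch_drift_sd sd of the per-batch additive drift on all log2
#'   ratios; `n_batches` batches are assigned by subject blocks.
#' @param n_batches number of acquisition batches.
#' @param seed integer seed.
#' @return A list of class `srm_sim_params`.
#' @export
srm_sim_params <- function(n_pairs = 43L, transitions_per_peptide = 3L,
                           heavy_area = 1e5,
                           planted_ratios = c("P23142-4" = 0.85),
                           base_log2_ratio = 0,
                           biological_sd = 0.25, housekeeping_sd = 0.05,
                           noise_sd = 0.1,
                           batch_drift_sd = 0.2, n_batches = 2L,
                           seed = 1L) {
  stopifnot(n_pairs >= 1, transitions_per_peptide >= 1, heavy_area > 0,
            all(planted_ratios > 0), biological_sd >= 0, noise_sd >= 0,
            housekeeping_sd >= 0, batch_drift_sd >= 0, n_batches >= 1)
  structure(list(
    n_pairs = as.integer(n_pairs),
    transitions_per_peptide = as.integer(transitions_per_peptide),
    heavy_area = heavy_area, planted_ratios = planted_ratios,
    base_log2_ratio = base_log2_ratio,
    biological_sd = biological_sd, housekeeping_sd = housekeeping_sd,
    noise_sd = noise_sd,
    batch_drift_sd = batch_drift_sd, n_batches = as.integer(n_batches),
    seed = as.integer(seed)
  ), class = "srm_sim_params")
}

#' Simulate an SRM transition table with ground truth
#'
#' Heavy area = spike level x a per-transition response factor; light area
#' = heavy x 2^(subject analyte log2 ratio + batch drift + measurement
#' noise). The housekeeping protein carries ratio 1 and the same drift, so
#' housekeeping normalization can remove it.
#'
#' @param params an [srm_sim_params()].
#' @return A list: `table` (validated `srm_table`), `metadata` (one row per
#'   subject: `sample_id`, `subject_id`, `group`, `pair_id`, `replicate`,
#'   `batch`), and `truth` (planted log2 ratios per protein, per-batch
#'   drifts, per-subject analyte levels).
#' @export
simulate_srm <- function(params = srm_sim_params()) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(params$seed)
  assay <- srm_assay_peptides()
  proteins <- unique(assay$protein)
  ratios <- stats::setNames(rep(1, length(proteins)), proteins)
  ratios[names(params$planted_ratios)] <- params$planted_ratios

  ns <- 2L * params$n_pairs
  subj <- sprintf("V%03d", seq_len(ns))
  group <- rep(c("case", "control"), params$n_pairs)
  pair <- rep(sprintf("P%02d", seq_len(params$n_pairs)), each = 2)
  batch <- paste0("B", ((seq_len(ns) - 1) %/% ceiling(ns / params$n_batches)) + 1)
  drift <- stats::setNames(stats::rnorm(params$n_batches, 0, params$batch_drift_sd),
                           paste0("B", seq_len(params$n_batches)))
  metadata <- tibble::tibble(sample_id = subj, subject_id = subj,
                             group = group, pair_id = pair,
                             replicate = 1L, batch = batch)

  # subject-level analyte log2 ratio per protein; housekeeping references
  # (C1s, A1BG) are selected for consistency, hence their smaller subject sd
  housekeeping <- c("P09871", "P04217")
  subj_level <- sapply(proteins, function(pr) {
    sdp <- if (pr %in% housekeeping) params$housekeeping_sd else params$biological_sd
    params$base_log2_ratio + log2(ratios[pr]) * (group == "case") +
      stats::rnorm(ns, 0, sdp)
  })  # ns x proteins
  rownames(subj_level) <- subj

  trans <- assay[rep(seq_len(nrow(assay)), each = params$transitions_per_peptide), ]
  trans$fragment <- paste0("y", rep(seq_len(params$transitions_per_peptide) + 2,
                                    nrow(assay)))
  response <- 2^stats::rnorm(nrow(trans), 0, 0.5)  # per-transition response

  rows <- vector("list", nrow(trans))
  for (t_i in seq_len(nrow(trans))) {
    pr <- trans$protein[t_i]
    heavy <- params$heavy_area * response[t_i]
    light <- heavy * 2^(subj_level[, pr] + drift[batch] +
                          stats::rnorm(ns, 0, params$noise_sd))
    rows[[t_i]] <- tibble::tibble(
      protein = pr, peptide = trans$peptide[t_i], fragment = trans$fragment[t_i],
      sample_id = rep(subj, 2), batch = rep(batch, 2),
      label = rep(c("light", "heavy"), each = ns),
      area = c(unname(light), rep(unname(heavy), ns))
    )
  }
  table <- validate_srm_table(dplyr::bind_rows(rows))
  list(table = table, metadata = metadata,
       truth = list(log2_ratios = log2(ratios), drift = drift,
                    subject_levels = subj_level))
}

#' Benchmark data set with three complementary panel proteins
#'
#' Generates a subject-level log2 matrix in which the case group splits into
#' three equally sized latent subtypes, each elevated by `delta` in exactly
#' one of three informative proteins (complementary, additive-logit-style
#' signal: each addition to a panel contributes a disjoint slice of cases),
#' among `n_null` null proteins. Used for panel-recovery studies.
#'
#' @param n_pairs matched pairs.
#' @param n_null number of null proteins.
#' @param delta subtype elevation (log2 units).
#' @param sd unit within-group noise sd.
#' @param seed integer seed.
#' @return A list: `matrix` (subject-level log2 [lfq_matrix()]) and `truth`
#'   (the informative protein names and subtype assignment).
#' @export
simulate_panel_benchmark <- function(n_pairs = 43L, n_null = 97L, delta = 4,
                                     sd = 1, seed = 1L) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  ns <- 2L * n_pairs
  group <- rep(c("case", "control"), n_pairs)
  subj <- sprintf("S%03d", seq_len(ns))
  informative <- c("PANEL1", "PANEL2", "PANEL3")
  prot <- c(informative, sprintf("NULL%03d", seq_len(n_null)))
  v <- matrix(stats::rnorm(length(prot) * ns, 0, sd), length(prot), ns,
              dimnames = list(prot, subj))
  case_idx <- which(group == "case")
  subtype <- rep(1:3, length.out = length(case_idx))
  for (k in 1:3) {
    v[informative[k], case_idx[subtype == k]] <-
      v[informative[k], case_idx[subtype == k]] + delta
  }
  metadata <- tibble::tibble(sample_id = subj, subject_id = subj,
                             group = group,
                             pair_id = rep(sprintf("P%02d", seq_len(n_pairs)),
                                           each = 2),
                             replicate = 1L, batch = "B1")
  records <- tibble::tibble(protein = prot, protein_ids = as.list(prot),
                            is_reverse = FALSE, only_by_site = FALSE,
                            unique_razor_peptides = 5L, is_contaminant = FALSE)
  list(matrix = lfq_matrix(v, records, metadata, scale = "log2"),
       truth = list(informative = informative,
                    subtype = stats::setNames(subtype, subj[case_idx])))
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes the simulated discovery protein-groups table (MaxQuant dialect,
#' tab-separated, zeros for missing cells), the sample-metadata CSV and the
#' SRM transition CSV — exactly the formats the readers consume. Byte-stable
#' under a fixed seed.
#'
#' @param out_dir output directory (created if needed).
#' @param discovery a [discovery_sim_params()].
#' @param srm an [srm_sim_params()].
#' @return Named character vector of the written paths, invisibly; the
#'   simulations themselves are attached as the `"simulations"` attribute.
#' @export
write_fixture_bundle <- function(out_dir,
                                 discovery = discovery_sim_params(),
                                 srm = srm_sim_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_d <- simulate_discovery(discovery)
  sim_s <- simulate_srm(srm)

  paths <- c(protein_groups = file.path(out_dir, "proteinGroups.txt"),
             metadata = file.path(out_dir, "sample_metadata.csv"),
             srm = file.path(out_dir, "srm_transitions.csv"),
             srm_metadata = file.path(out_dir, "srm_sample_metadata.csv"))

  mat <- sim_d$matrix
  v <- mat$values
  v[is.na(v)] <- 0  # MaxQuant writes undetected intensities as 0
  tab <- data.frame(
    `Protein IDs` = vapply(mat$records$protein_ids, paste, character(1),
                           collapse = ";"),
    Reverse = ifelse(mat$records$is_reverse, "+", ""),
    `Only identified by site` = ifelse(mat$records$only_by_site, "+", ""),
    `Unique + razor peptides` = mat$records$unique_razor_peptides,
    `Sequence coverage [%]` = mat$records$sequence_coverage_pct,
    check.names = FALSE
  )
  iv <- as.data.frame(signif(v, 8))
  names(iv) <- paste0("Intensity ", colnames(v))
  utils::write.table(cbind(tab, iv), paths["protein_groups"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  readr::write_csv(sim_d$metadata, paths["metadata"], progress = FALSE)
  srm_out <- dplyr::mutate(as.data.frame(sim_s$table[
    , c("protein", "peptide", "fragment", "label", "sample_id", "batch", "area")
  ]), area = signif(.data$area, 8))
  readr::write_csv(srm_out, paths["srm"], progress = FALSE)
  readr::write_csv(sim_s$metadata, paths["srm_metadata"], progress = FALSE)
  attr(paths, "simulations") <- list(discovery = sim_d, srm = sim_s)
  invisible(paths)
}
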