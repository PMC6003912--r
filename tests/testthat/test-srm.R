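# Light/heavy ratios, housekeeping normalization, median polish, group
# comparison.

test_that("light/heavy ratios are exact and partnerless rows are counted", {
  tbl <- validate_srm_table(tibble::tibble(
    protein = "P1", peptide = "PEP",
    fragment = rep(c("y3", "y4", "y5"), each = 2),
    label = rep(c("light", "heavy"), 3),
    sample_id = "V1", batch = "B1",
    area = c(2000, 1000, 500, 500, 300, 0)))
  ratios <- light_heavy_log_ratio(tbl)
  expect_equal(nrow(ratios), 2)  # y5 dropped: heavy area 0
  expect_equal(ratios$log2_ratio[ratios$fragment == "y3"], 1)
  expect_equal(ratios$log2_ratio[ratios$fragment == "y4"], 0)
  expect_equal(attr(ratios, "dropped"), 1)
})

test_that("synthetic noise-free ratios are recovered exactly", {
  sim <- simulate_srm(srm_sim_params(n_pairs = 3, biological_sd = 0, housekeeping_sd = 0,
                                     noise_sd = 0, batch_drift_sd = 0, seed = 5))
  ratios <- light_heavy_log_ratio(sim$table)
  truth <- sim$truth$log2_ratios
  for (pr in names(truth)) {
    grp <- sim$metadata$group[match(ratios$sample_id[ratios$protein == pr],
                                    sim$metadata$sample_id)]
    vals <- ratios$log2_ratio[ratios$protein == pr]
    expect_equal(unique(round(vals[grp == "case"] - vals[grp == "control"], 10)),
                 round(truth[[pr]], 10))
  }
})

test_that("housekeeping normalization cancels sample shifts and is idempotent", {
  sim <- simulate_srm(srm_sim_params(n_pairs = 4, noise_sd = 0,
                                     batch_drift_sd = 0, seed = 7))
  ratios <- light_heavy_log_ratio(sim$table)
  shifted <- dplyr::mutate(ratios, log2_ratio = .data$log2_ratio +
                             ifelse(.data$sample_id == "V001", 0.5, 0))
  norm_shifted <- normalize_to_housekeeping(shifted)
  norm_plain <- normalize_to_housekeeping(ratios)
  expect_equal(norm_shifted$log2_ratio, norm_plain$log2_ratio)
  again <- normalize_to_housekeeping(norm_plain)
  expect_equal(again$log2_ratio, norm_plain$log2_ratio)
  missing_hk <- dplyr::filter(ratios, .data$protein != "P09871")
  expect_error(normalize_to_housekeeping(missing_hk), "housekeeping")
})

test_that("planted batch drift is removed by housekeeping normalization", {
  params <- srm_sim_params(n_pairs = 20, noise_sd = 0.05, biological_sd = 0.1,
                           batch_drift_sd = 0.3, n_batches = 2, seed = 11)
  sim <- simulate_srm(params)
  ratios <- light_heavy_log_ratio(sim$table)
  normed <- normalize_to_housekeeping(ratios)
  analyte <- dplyr::filter(normed, .data$protein == "P06396")
  batch_means <- tapply(analyte$log2_ratio, analyte$batch, mean)
  raw <- dplyr::filter(ratios, .data$protein == "P06396")
  raw_batch_means <- tapply(raw$log2_ratio, raw$batch, mean)
  drift_gap <- abs(diff(as.numeric(sim$truth$drift)))
  # batch means also carry subject-level noise: se(diff) ~ 0.1*sqrt(2/20)
  expect_lt(abs(abs(diff(as.numeric(raw_batch_means))) - drift_gap), 0.1)
  expect_lt(abs(diff(as.numeric(batch_means))), 0.1)
})

test_that("median polish matches the hand-iterated 2x2 example and reconstructs", {
  mp <- median_polish(matrix(c(1, 3, 2, 5), 2, 2))
  expect_equal(mp$overall, 2.75)
  expect_equal(unname(mp$row_effects), c(-1.25, 1.25))
  expect_equal(unname(mp$col_effects), c(-0.75, 0.75))
  expect_equal(unname(mp$residuals),
               matrix(c(0.25, -0.25, -0.25, 0.25), 2, 2), ignore_attr = TRUE)

  # exactly additive matrix: zero residuals after one sweep
  r <- c(0, 1, 2); cc <- c(0, -1)
  add <- outer(r, cc, "+") + 3
  mpa <- median_polish(add)
  expect_equal(max(abs(mpa$residuals)), 0)

  # reconstruction identity on random matrices, with permutation equivariance
  set.seed(87)
  m <- matrix(rnorm(30), 5, 6)
  mpr <- median_polish(m)
  recon <- mpr$overall + outer(mpr$row_effects, mpr$col_effects, "+") + mpr$residuals
  expect_equal(recon, m, ignore_attr = TRUE)
  perm_r <- sample(5); perm_c <- sample(6)
  mpp <- median_polish(m[perm_r, perm_c])
  expect_equal(mpp$overall, mpr$overall)
  expect_equal(unname(mpp$col_effects), unname(mpr$col_effects[perm_c]))
  expect_error(median_polish(matrix(NA_real_, 2, 1)), "all-missing")
})

test_that("group comparison is exact in degenerate settings and BH behaves", {
  summaries <- tibble::tibble(
    protein = rep(c("A", "B"), each = 8),
    sample_id = rep(sprintf("V%02d", 1:8), 2),
    log2_summary = c(rep(c(1, 1, 2, 2), 2), rep(0, 4), rep(-1, 4)),
    n_transitions_used = 3L)
  meta <- tibble::tibble(sample_id = sprintf("V%02d", 1:8),
                         group = rep(c("case", "control"), each = 4))
  cfg <- srm_config(exclude_from_family = character(0))
  # protein A: identical distributions in both groups
  resA <- srm_group_compare(dplyr::filter(summaries, protein == "A"), meta, cfg)
  expect_equal(resA$log2_ratio, 0)
  expect_equal(resA$p_value, 1)
  expect_equal(resA$p_adjusted, resA$p_value)  # single target: BH is identity
  res <- srm_group_compare(summaries, meta, cfg)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
})

test_that("include lists restrict the transitions entering the statistics", {
  sim <- simulate_srm(srm_sim_params(n_pairs = 6, seed = 13))
  res <- srm_verify(sim$table, sim$metadata, srm_config())
  fb <- res[res$protein == "P23142-4", ]
  expect_equal(fb$n_transitions_used, 3)  # DLLLTVK only, 3 transitions
  res_all <- srm_verify(sim$table, sim$metadata,
                        srm_config(peptide_include_list = list()))
  expect_equal(res_all$n_transitions_used[res_all$protein == "P23142-4"], 6)
})

test_that("the verification chain flags the planted protein and nothing else", {
  sim <- simulate_srm(srm_sim_params(seed = 17))
  res <- srm_verify(sim$table, sim$metadata)
  fam <- res[res$in_family, ]
  expect_equal(fam$protein[fam$p_adjusted < 0.05], "P23142-4")
  fb <- fam[fam$protein == "P23142-4", ]
  expect_true(fb$ci_low <= 0.85 && 0.85 <= fb$ci_high)
  expect_true(all(is.na(res$p_adjusted[!res$in_family])))
  expect_s3_class(autoplot(res, proteins = "P23142-4"), "ggplot")
})
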