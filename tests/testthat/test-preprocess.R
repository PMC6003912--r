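# Identification filtering, log2 transform, valid-value filtering,
# downshifted-normal imputation, replicate averaging.

make_raw_matrix <- function(values, records, samples = NULL) {
  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = colnames(values))
  }
  lfq_matrix(values, records, samples, scale = "raw")
}

test_that("identification filtering applies all rules and reports counts", {
  # 10 rows: 2 reverse, 1 only-by-site, 2 single-peptide, one overlap
  # (row 2 is reverse AND single-peptide)
  records <- tibble::tibble(
    protein = paste0("p", 1:10),
    protein_ids = as.list(paste0("p", 1:10)),
    is_reverse = c(TRUE, TRUE, rep(FALSE, 8)),
    only_by_site = c(rep(FALSE, 2), TRUE, rep(FALSE, 7)),
    unique_razor_peptides = c(5L, 1L, 5L, 1L, rep(3L, 6)),
    is_contaminant = FALSE)
  v <- matrix(2, 10, 2, dimnames = list(paste0("p", 1:10), c("s1", "s2")))
  x <- make_raw_matrix(v, records)
  out <- filter_identifications(x, preprocess_config())
  # brute-force set evaluation of the same rules
  keep_oracle <- !(records$is_reverse | records$only_by_site |
                     records$unique_razor_peptides < 2)
  expect_equal(rownames(out$values), paste0("p", 1:10)[keep_oracle])
  rep_tbl <- attr(out, "filter_report")
  expect_equal(rep_tbl$n[rep_tbl$rule == "reverse"], 2)
  expect_equal(rep_tbl$n[rep_tbl$rule == "only_by_site"], 1)
  expect_equal(rep_tbl$n[rep_tbl$rule == "min_peptides"], 2)
  expect_equal(rep_tbl$n[rep_tbl$rule == "removed_total"], 10 - sum(keep_oracle))
  # bookkeeping identity and idempotence
  expect_equal(nrow(out$values) + rep_tbl$n[rep_tbl$rule == "removed_total"], 10)
  again <- filter_identifications(out, preprocess_config())
  expect_equal(again$values, out$values)
})

test_that("log2 transform maps present cells and preserves missingness", {
  records <- tibble::tibble(protein = "p1", protein_ids = list("p1"),
                            is_reverse = FALSE, only_by_site = FALSE,
                            unique_razor_peptides = 3L, is_contaminant = FALSE)
  v <- matrix(c(8, 1, NA), 1, 3, dimnames = list("p1", c("a", "b", "c")))
  x <- make_raw_matrix(v, records)
  out <- log2_transform(x)
  expect_equal(unname(out$values[1, ]), c(3, 0, NA))
  expect_equal(out$scale, "log2")
  expect_error(log2_transform(out), "already")
})

test_that("valid-value filtering is inclusive at the 50% boundary and matches a mask scan", {
  set.seed(7)
  p <- 100; n <- 20
  v <- matrix(rnorm(p * n, 20), p, n,
              dimnames = list(sprintf("q%03d", 1:p), sprintf("s%02d", 1:n)))
  v[runif(p * n) < 0.45] <- NA
  records <- tibble::tibble(protein = rownames(v), protein_ids = as.list(rownames(v)),
                            is_reverse = FALSE, only_by_site = FALSE,
                            unique_razor_peptides = 3L, is_contaminant = FALSE)
  x <- lfq_matrix(v, records, tibble::tibble(sample_id = colnames(v)), "log2")
  out <- filter_valid_fraction(x, preprocess_config())
  keep_oracle <- apply(v, 1, function(r) sum(!is.na(r)) >= 0.5 * n)
  expect_equal(rownames(out$values), rownames(v)[keep_oracle])

  # boundary: 2 of 4 present is kept, 1 of 4 removed
  v2 <- matrix(c(20, 21, NA, NA, 20, NA, NA, NA), 2, 4, byrow = TRUE,
               dimnames = list(c("kept", "dropped"), paste0("s", 1:4)))
  x2 <- lfq_matrix(v2, records[1:2, ] |> dplyr::mutate(protein = rownames(v2)),
                   tibble::tibble(sample_id = colnames(v2)), "log2")
  out2 <- filter_valid_fraction(x2, preprocess_config())
  expect_equal(rownames(out2$values), "kept")
})

test_that("imputed draws follow the downshifted normal and touch only missing cells", {
  set.seed(3)
  n_present <- 2000; n_missing <- 10000
  col <- c(rnorm(n_present, mean = 20, sd = 1), rep(NA, n_missing))
  v <- matrix(col, ncol = 1, dimnames = list(NULL, "s1"))
  rn <- sprintf("r%05d", seq_along(col))
  rownames(v) <- rn
  records <- tibble::tibble(protein = rn, protein_ids = as.list(rn),
                            is_reverse = FALSE, only_by_site = FALSE,
                            unique_razor_peptides = 3L, is_contaminant = FALSE)
  x <- lfq_matrix(v, records, tibble::tibble(sample_id = "s1"), "log2")
  out <- impute_downshifted_normal(x, preprocess_config(seed = 5))
  expect_false(anyNA(out$values))
  # present cells untouched (masked equality)
  expect_equal(out$values[!is.na(v)], v[!is.na(v)])
  imputed <- out$values[is.na(v)]
  m <- mean(col, na.rm = TRUE); s <- sd(col, na.rm = TRUE)
  # moments of Normal(m - 1.8 s, (0.3 s)^2), 3 standard errors
  se_mean <- 0.3 * s / sqrt(n_missing)
  expect_lt(abs(mean(imputed) - (m - 1.8 * s)), 3 * se_mean)
  se_sd <- 0.3 * s / sqrt(2 * (n_missing - 1))
  expect_lt(abs(sd(imputed) - 0.3 * s), 3 * se_sd)

  # determinism and identity on complete data
  out2 <- impute_downshifted_normal(x, preprocess_config(seed = 5))
  expect_identical(out$values, out2$values)
  complete <- impute_downshifted_normal(out, preprocess_config(seed = 9))
  expect_identical(complete$values, out$values)
})

test_that("imputation errors on a column with fewer than two present values", {
  v <- matrix(c(20, NA, NA, 21, 22, 23), 3, 2,
              dimnames = list(paste0("p", 1:3), c("bad", "good")))
  records <- tibble::tibble(protein = paste0("p", 1:3),
                            protein_ids = as.list(paste0("p", 1:3)),
                            is_reverse = FALSE, only_by_site = FALSE,
                            unique_razor_peptides = 3L, is_contaminant = FALSE)
  x <- lfq_matrix(v, records, tibble::tibble(sample_id = colnames(v)), "log2")
  expect_error(impute_downshifted_normal(x, preprocess_config()), "bad")
})

test_that("replicate averaging equals per-subject means and passes singles through", {
  sim <- simulate_discovery(discovery_sim_params(n_pairs = 5, n_proteins = 30, seed = 21))
  pre <- impute_downshifted_normal(
    filter_valid_fraction(log2_transform(filter_identifications(sim$matrix)),
                          preprocess_config()),
    preprocess_config(seed = 2))
  avg <- average_replicates(pre)
  expect_equal(ncol(avg$values), 10)  # one column per subject
  for (s in colnames(avg$values)) {
    cols <- pre$samples$sample_id[pre$samples$subject_id == s]
    expect_equal(avg$values[, s], rowMeans(pre$values[, cols, drop = FALSE]))
  }
  # single replicate value passes through
  one <- filter_proteins(pre, 1)
  keep <- pre$samples$replicate == 1
  single <- lfq_matrix(pre$values[1, keep, drop = FALSE], pre$records[1, ],
                       pre$samples[keep, ], "log2")
  avg1 <- average_replicates(single)
  expect_equal(unname(avg1$values[1, ]), unname(pre$values[1, keep]))
})

test_that("full preprocessing chain enforces order and reports bookkeeping", {
  sim <- simulate_discovery(discovery_sim_params(n_pairs = 6, n_proteins = 40, seed = 31))
  out <- preprocess(sim$matrix, preprocess_config(seed = 4))
  expect_equal(ncol(out$values), 12)
  expect_false(anyNA(out$values))
  rep_tbl <- attr(out, "filter_report")
  n_in <- rep_tbl$n[rep_tbl$rule == "input_rows"]
  removed <- sum(rep_tbl$n[rep_tbl$rule %in% c("removed_total", "below_valid_fraction")])
  expect_equal(n_in - removed, nrow(out$values))
})

test_that("under MNAR, imputed values fall below the column mean on average", {
  sim <- simulate_discovery(discovery_sim_params(
    n_pairs = 10, n_proteins = 80, missing_midpoint = 22, seed = 41))
  filt <- filter_valid_fraction(
    log2_transform(filter_identifications(sim$matrix)), preprocess_config())
  imp <- impute_downshifted_normal(filt, preprocess_config(seed = 6))
  mask <- attr(imp, "imputed_mask")
  col_means <- colMeans(filt$values, na.rm = TRUE)
  imputed_vs_mean <- imp$values - rep(col_means, each = nrow(imp$values))
  expect_lt(mean(imputed_vs_mean[mask]), 0)
})
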