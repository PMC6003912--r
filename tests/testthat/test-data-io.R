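# MaxQuant-dialect protein-groups reading, metadata validation, SRM table
# validation, and results-table round trips.

write_pg_fixture <- function(path, rows, samples = c("s1", "s2")) {
  header <- c("Protein IDs", "Reverse", "Only identified by site",
              "Unique + razor peptides", paste0("Intensity ", samples))
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, character(1), collapse = "\t"))
  writeLines(lines, path)
  path
}

test_that("protein-groups parsing passes flags through and treats zero as missing", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_pg_fixture(path, list(
    c("A1", "", "", "4", "100.5", "200"),
    c("REV__B1", "+", "", "3", "50", "60"),
    c("C1;C2", "", "+", "2", "0", "80"),
    c("D1", "", "", "1", "10", "0"),
    c("REV__E1", "", "", "5", "20", "30"),   # decoy by prefix only
    c("F1", "", "", "6", "1", "2")
  ))
  mat <- read_protein_groups(path)
  expect_equal(nrow(mat$records), 6)
  expect_equal(sum(mat$records$is_reverse), 2)
  expect_equal(mat$records$protein, c("A1", "REV__B1", "C1", "D1", "REV__E1", "F1"))
  expect_equal(mat$records$protein_ids[[3]], c("C1", "C2"))
  # zeros became missing, everything else parsed on the raw scale
  expect_true(is.na(mat$values["C1", "s1"]))
  expect_true(is.na(mat$values["D1", "s2"]))
  expect_equal(mat$values["A1", "s1"], 100.5)
  expect_equal(mat$scale, "raw")
})

test_that("protein-groups reader reports format errors with coordinates", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_pg_fixture(path, list(c("A1", "", "", "2", "oops", "2")))
  expect_error(read_protein_groups(path), "row 1")
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Protein IDs\tReverse\tIntensity s1", "A\t\t1"), path2)
  expect_error(read_protein_groups(path2), "Only identified by site")
  path3 <- withr::local_tempfile(fileext = ".txt")
  write_pg_fixture(path3, list(c("A1", "", "", "2", "1", "2")),
                   samples = c("s1", "s1"))
  expect_error(read_protein_groups(path3), "duplicate sample")
})

test_that("sample metadata validation enforces the pairing invariant", {
  meta <- tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2"),
    subject_id = c("A", "A", "B", "B"),
    group = c("case", "case", "control", "control"),
    pair_id = "P1", replicate = c(1L, 2L, 1L, 2L), batch = "B1")
  out <- validate_sample_metadata(meta)
  expect_equal(nrow(out), 4)

  bad <- meta
  bad$group <- "case"  # two cases in one pair
  expect_error(validate_sample_metadata(bad), "P1")
  bad2 <- meta
  bad2$group[1:2] <- "unknown"
  expect_error(validate_sample_metadata(bad2), "unknown")
})

test_that("86-subject quadruplicate design yields 344 records and 43 pairs", {
  sim <- simulate_discovery(discovery_sim_params(seed = 11))
  expect_equal(nrow(sim$metadata), 344)
  expect_equal(length(unique(sim$metadata$pair_id)), 43)
  expect_silent(validate_sample_metadata(sim$metadata))
})

test_that("SRM table validation flags unpaired light rows and rejects duplicates", {
  tbl <- tibble::tibble(
    protein = "P1", peptide = "PEP", fragment = rep(c("y3", "y4"), each = 2),
    label = c("light", "heavy", "light", "heavy"),
    sample_id = "V1", batch = "B1", area = c(10, 5, 8, 4))
  out <- validate_srm_table(tbl)
  expect_s3_class(out, "srm_table")
  expect_false(any(out$unpaired))

  orphan <- tbl[c(1, 2, 3), ]  # y4 light lacks its heavy partner
  out2 <- validate_srm_table(orphan)
  expect_equal(sum(out2$unpaired), 1)
  expect_equal(nrow(out2), 3)  # flagged, not dropped

  expect_error(validate_srm_table(dplyr::mutate(tbl, area = -1)), "negative")
  expect_error(validate_srm_table(tbl[c(1, 1, 2), ]), "duplicate")
})

test_that("fixture bundle round-trips through the readers", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(
    dir, discovery = discovery_sim_params(n_pairs = 4, n_proteins = 25, seed = 3),
    srm = srm_sim_params(n_pairs = 3, seed = 3))
  sims <- attr(paths, "simulations")

  mat <- read_protein_groups(paths["protein_groups"])
  truth_mat <- sims$discovery$matrix
  expect_equal(dim(mat$values), dim(truth_mat$values))
  present <- !is.na(truth_mat$values)
  expect_equal(mat$values[present], signif(truth_mat$values[present], 8))
  expect_equal(is.na(mat$values), is.na(truth_mat$values))
  expect_equal(mat$records$is_reverse, truth_mat$records$is_reverse)

  meta <- read_sample_metadata(paths["metadata"])
  expect_equal(meta$sample_id, sims$discovery$metadata$sample_id)

  srm <- read_srm_table(paths["srm"])
  expect_equal(nrow(srm), nrow(sims$srm$table))
  expect_equal(srm$area, signif(sims$srm$table$area, 8))
})

test_that("fixture bundle is byte-stable under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_fixture_bundle(d1, discovery_sim_params(n_pairs = 3, n_proteins = 15, seed = 9),
                             srm_sim_params(n_pairs = 2, seed = 9))
  p2 <- write_fixture_bundle(d2, discovery_sim_params(n_pairs = 3, n_proteins = 15, seed = 9),
                             srm_sim_params(n_pairs = 2, seed = 9))
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
})

test_that("differential table writing renders sub-resolution FDR distinctly and round-trips", {
  res <- tibble::tibble(protein = c("A", "B", "C"),
                        log2_fc = c(-0.27, 0.22, 0.1),
                        d = c(3, 2, 1),
                        p_value = c(0.0001, 0.01, 0.5),
                        fdr = c(0.00004, 0.2, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_diff_table(res, path)
  lines <- readLines(path)
  expect_equal(length(lines), 4)  # header + 3 rows
  expect_match(lines[2], "<1e-04")
  back <- read_diff_table(path)
  expect_true(back$fdr_censored[1])
  expect_equal(back$fdr[-1], res$fdr[-1], tolerance = 1e-6)
  expect_equal(back$log2_fc, res$log2_fc)
})
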