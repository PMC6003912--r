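# Independent brute-force oracles used against the package implementations.

# O(n^2) pair-counting AUROC
auroc_pair_count <- function(scores, labels) {
  y <- as.integer(labels == "case" | labels == 1 | labels == TRUE)
  cases <- scores[y == 1]; controls <- scores[y == 0]
  total <- 0
  for (a in cases) for (b in controls) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(cases) * length(controls))
}

# pooled-null permutation p-values by explicit enumeration of all group-label
# assignments, computed protein by protein with the scalar statistic
exhaustive_perm_p <- function(V, n_case, alpha1, alpha2) {
  n <- ncol(V); p <- nrow(V)
  combos <- utils::combn(n, n_case)
  d_obs <- vapply(seq_len(p), function(i) {
    tstat_family(V[i, seq_len(n_case)], V[i, -seq_len(n_case)], alpha1, alpha2)
  }, numeric(1))
  d_null <- c()
  for (ci in seq_len(ncol(combos))) {
    g1 <- combos[, ci]
    d_null <- c(d_null, vapply(seq_len(p), function(i) {
      tstat_family(V[i, g1], V[i, -g1], alpha1, alpha2)
    }, numeric(1)))
  }
  vapply(d_obs, function(d) (1 + sum(d_null >= d)) / (1 + length(d_null)),
         numeric(1))
}

# bootstrap (cases and controls resampled with replacement) SE of the AUROC
bootstrap_auc_se <- function(cases, controls, n_boot, seed) {
  set.seed(seed)
  m <- length(cases); n <- length(controls)
  ci <- matrix(sample(m, n_boot * m, replace = TRUE), n_boot)
  ki <- matrix(sample(n, n_boot * n, replace = TRUE), n_boot)
  auc <- numeric(n_boot)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    a <- cases[ci[, i]]; b <- controls[ki[, j]]
    auc <- auc + (a > b) + 0.5 * (a == b)
  }
  stats::sd(auc / (m * n))
}

# a small ready-made subject-level matrix with planted group difference
toy_subject_matrix <- function(n_pairs = 10, n_proteins = 20, delta = 0,
                               delta_rows = integer(0), sd = 1, seed = 1) {
  set.seed(seed)
  ns <- 2 * n_pairs
  group <- rep(c("case", "control"), n_pairs)
  v <- matrix(rnorm(n_proteins * ns, 0, sd), n_proteins, ns)
  if (length(delta_rows) > 0) {
    v[delta_rows, group == "case"] <- v[delta_rows, group == "case"] + delta
  }
  prot <- sprintf("T%03d", seq_len(n_proteins))
  subj <- sprintf("S%03d", seq_len(ns))
  dimnames(v) <- list(prot, subj)
  records <- tibble::tibble(protein = prot, protein_ids = as.list(prot),
                            is_reverse = FALSE, only_by_site = FALSE,
                            unique_razor_peptides = 5L, is_contaminant = FALSE)
  samples <- tibble::tibble(sample_id = subj, subject_id = subj, group = group,
                            pair_id = rep(sprintf("P%02d", seq_len(n_pairs)),
                                          each = 2),
                            replicate = 1L, batch = "B1")
  lfq_matrix(v, records, samples, scale = "log2")
}
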