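#' Parameters of the reproducibility-optimized differential test
#'
#' The test statistic family is d = |m1 - m2| / (alpha1 + alpha2 * s), with
#' s the Welch-type standard error sqrt(s1^2/n1 + s2^2/n2). The
#' regularization pair (alpha1, alpha2) is chosen to maximize the bootstrap
#' reproducibility of top-ranked protein lists against a permuted-label
#' baseline; p-values and FDR then come from group-label permutations.
#'
#' @param n_permutations number of group-label permutations for p/FDR.
#' @param n_bootstrap number of bootstrap dataset pairs for the
#'   reproducibility optimization.
#' @param alpha1_grid candidate alpha1 values used with alpha2 = 1.
#' @param alpha2_choices subset of c(0, 1); including 0 adds the plain
#'   absolute mean-difference statistic (|m|, scale-free in alpha1) as a
#'   candidate.
#' @param top_list_sizes candidate top-list sizes K (capped at the protein
#'   count at run time).
#' @param seed integer seed; all resampling is reproducible under it.
#' @return A list of class `rots_params`.
#' @export
rots_params <- function(n_permutations = 1000L,
                        n_bootstrap = 500L,
                        alpha1_grid = c(0, 0.01, 0.05, 0.1, 0.2, 0.5, 1, 2, 5),
                        alpha2_choices = c(0, 1),
                        top_list_sizes = c(25L, 50L, 100L, 200L),
                        seed = 1L) {
  stopifnot(n_permutations >= 1, n_bootstrap >= 2,
            length(alpha1_grid) > 0, all(alpha1_grid >= 0),
            all(alpha2_choices %in% c(0, 1)), length(top_list_sizes) > 0)
  structure(list(
    n_permutations = as.integer(n_permutations),
    n_bootstrap = as.integer(n_bootstrap),
    alpha1_grid = sort(unique(alpha1_grid)),
    alpha2_choices = sort(unique(alpha2_choices)),
    top_list_sizes = sort(unique(as.integer(top_list_sizes))),
    seed = as.integer(seed)
  ), class = "rots_params")
}

#' t-type statistic family for two-group comparison
#'
#' d = |mean(g1) - mean(g2)| / (alpha1 + alpha2 * s), where
#' s = sqrt(var(g1)/n1 + var(g2)/n2). alpha = (0, 1) gives the absolute
#' Welch t statistic; alpha = (1, 0) the absolute mean difference.
#'
#' @param group1_values,group2_values numeric vectors, each with at least two
#'   finite values.
#' @param alpha1,alpha2 regularization constants, not both zero.
#' @return The nonnegative statistic d.
#' @export
tstat_family <- function(group1_values, group2_values, alpha1, alpha2) {
  if (alpha1 == 0 && alpha2 == 0) {
    stop("alpha1 and alpha2 cannot both be zero", call. = FALSE)
  }
  g1 <- group1_values[is.finite(group1_values)]
  g2 <- group2_values[is.finite(group2_values)]
  if (length(g1) < 2 || length(g2) < 2) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  m <- abs(mean(g1) - mean(g2))
  s <- sqrt(stats::var(g1) / length(g1) + stats::var(g2) / length(g2))
  denom <- alpha1 + alpha2 * s
  if (denom == 0) {
    if (m == 0) return(0)
    stop("zero denominator with nonzero mean difference", call. = FALSE)
  }
  m / denom
}

# Per-protein |mean difference| and Welch SE for many (possibly weighted)
# column assignments at once. V is proteins x samples; W1/W0 are samples x B
# nonnegative weight (count) matrices for the two groups.
.group_stats_multi <- function(V, W1, W0) {
  V2 <- V * V
  n1 <- colSums(W1); n0 <- colSums(W0)
  S1 <- V %*% W1; S0 <- V %*% W0
  Q1 <- V2 %*% W1; Q0 <- V2 %*% W0
  M1 <- sweep(S1, 2, n1, "/"); M0 <- sweep(S0, 2, n0, "/")
  VAR1 <- sweep(Q1 - sweep(M1 * M1, 2, n1, "*"), 2, pmax(n1 - 1, 1), "/")
  VAR0 <- sweep(Q0 - sweep(M0 * M0, 2, n0, "*"), 2, pmax(n0 - 1, 1), "/")
  VAR1[VAR1 < 0] <- 0; VAR0[VAR0 < 0] <- 0
  list(m = abs(M1 - M0), diff = M1 - M0,
       se = sqrt(sweep(VAR1, 2, n1, "/") + sweep(VAR0, 2, n0, "/")))
}

# d matrix for one alpha from .group_stats_multi output; 0/0 -> 0
.d_from_stats <- function(st, alpha1, alpha2) {
  denom <- alpha1 + alpha2 * st$se
  d <- st$m / denom
  d[st$m == 0] <- 0
  d[is.infinite(d)] <- .Machine$double.xmax
  d
}

# candidate grid as a tibble of (alpha1, alpha2)
.alpha_candidates <- function(params) {
  grid <- tibble::tibble(alpha1 = numeric(), alpha2 = numeric())
  if (1 %in% params$alpha2_choices) {
    grid <- dplyr::bind_rows(grid,
      tibble::tibble(alpha1 = params$alpha1_grid, alpha2 = 1))
  }
  if (0 %in% params$alpha2_choices) {
    # with alpha2 = 0 the ranking is scale-free in alpha1: one candidate
    grid <- dplyr::bind_rows(grid, tibble::tibble(alpha1 = 1, alpha2 = 0))
  }
  grid
}

#' Optimize the statistic's regularization for bootstrap reproducibility
#'
#' For every candidate (alpha1, alpha2) and top-list size K, draws
#' `n_bootstrap` pairs of group-stratified bootstrap data sets and measures
#' the mean overlap proportion R of the two top-K lists; the same quantity
#' R0 is measured on group-label-permuted data. The pair maximizing
#' Z = (R - R0) / sd_bootstrap(R) is selected.
#'
#' @param x a subject-level [lfq_matrix()] with a `group` column in its
#'   sample metadata (or a plain matrix, in which case `groups` is required).
#' @param params a [rots_params()].
#' @param groups optional factor/character vector of `"case"`/`"control"`
#'   per column when `x` is a plain matrix.
#' @return A list with `alpha1`, `alpha2`, `k`, `z`, and the full `grid`
#'   tibble of (alpha1, alpha2, k, r, r0, z).
#' @export
rots_optimize <- function(x, params = rots_params(), groups = NULL) {
  V <- if (inherits(x, "lfq_matrix")) x$values else x
  g <- if (is.null(groups)) sample_groups(x) else factor(groups, c("control", "case"))
  idx_case <- which(g == "case"); idx_ctrl <- which(g == "control")
  stopifnot(length(idx_case) >= 3, length(idx_ctrl) >= 3)
  p <- nrow(V); n <- ncol(V)
  B <- params$n_bootstrap
  ks <- unique(pmin(params$top_list_sizes, p))

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(params$seed)

  # weight (count) matrices: columns 1..2B observed bootstrap pairs,
  # columns (2B+1)..4B permuted-label bootstrap pairs
  W1 <- matrix(0, n, 4 * B); W0 <- matrix(0, n, 4 * B)
  for (b in seq_len(2 * B)) {
    W1[idx_case, b] <- tabulate(sample(seq_along(idx_case), replace = TRUE),
                                nbins = length(idx_case))
    W0[idx_ctrl, b] <- tabulate(sample(seq_along(idx_ctrl), replace = TRUE),
                                nbins = length(idx_ctrl))
  }
  for (pairb in seq_len(B)) {
    perm <- sample(n)
    pc <- perm[seq_along(idx_case)]
    pk <- perm[-seq_along(idx_case)]
    for (half in 1:2) {
      b <- 2 * B + 2 * (pairb - 1) + half
      W1[pc, b] <- tabulate(sample(seq_along(pc), replace = TRUE),
                            nbins = length(pc))
      W0[pk, b] <- tabulate(sample(seq_along(pk), replace = TRUE),
                            nbins = length(pk))
    }
  }

  st <- .group_stats_multi(V, W1, W0)
  cand <- .alpha_candidates(params)
  grid <- list()
  for (ci in seq_len(nrow(cand))) {
    D <- .d_from_stats(st, cand$alpha1[ci], cand$alpha2[ci])
    RK <- matrix(0, length(ks), 2 * B)  # overlap per (K, pair)
    topranks <- apply(-D, 2, rank, ties.method = "first")
    for (pairb in seq_len(2 * B)) {
      r1 <- topranks[, 2 * pairb - 1]; r2 <- topranks[, 2 * pairb]
      for (ki in seq_along(ks)) {
        RK[ki, pairb] <- sum(r1 <= ks[ki] & r2 <= ks[ki]) / ks[ki]
      }
    }
    for (ki in seq_along(ks)) {
      r_obs <- RK[ki, seq_len(B)]
      r_null <- RK[ki, B + seq_len(B)]
      sdr <- stats::sd(r_obs)
      gap <- mean(r_obs) - mean(r_null)
      # perfectly reproducible lists have zero bootstrap sd: score them by
      # the sign of the observed-vs-null gap (infinitely strong evidence)
      z <- if (isTRUE(sdr > 0)) gap / sdr
        else if (gap != 0) sign(gap) * Inf else NA_real_
      grid[[length(grid) + 1]] <- tibble::tibble(
        alpha1 = cand$alpha1[ci], alpha2 = cand$alpha2[ci], k = ks[ki],
        r = mean(r_obs), r0 = mean(r_null), sd_r = sdr, z = z
      )
    }
  }
  grid <- dplyr::bind_rows(grid)
  if (all(is.na(grid$z))) {
    warning("reproducibility scores degenerate; falling back to alpha = (0, 1)")
    return(list(alpha1 = 0, alpha2 = 1, k = ks[1], z = NA_real_, grid = grid))
  }
  best <- grid[which.max(grid$z), ]
  list(alpha1 = best$alpha1, alpha2 = best$alpha2, k = best$k, z = best$z,
       grid = grid)
}

#' Permutation p-values and FDR for the selected statistic
#'
#' Recomputes all per-protein statistics under `n_permutations` random
#' group-label permutations. The p-value pools the permuted statistics over
#' all proteins, with an add-one correction:
#' p = (1 + #\{permuted d >= observed d\}) / (1 + total permuted count).
#' The FDR is the per-permutation exceedance count divided by the observed
#' rank, median across permutations, clipped to [0, 1] and monotonized along
#' decreasing d. When fewer distinct permutations than requested exist (tiny
#' designs) all distinct label assignments are enumerated instead, with a
#' warning.
#'
#' @inheritParams rots_optimize
#' @param alpha1,alpha2 the selected regularization (from [rots_optimize()]).
#' @return A tibble (`protein`, `d`, `p_value`, `fdr`) in matrix row order.
#' @export
rots_permutation_test <- function(x, alpha1, alpha2, params = rots_params(),
                                  groups = NULL) {
  V <- if (inherits(x, "lfq_matrix")) x$values else x
  g <- if (is.null(groups)) sample_groups(x) else factor(groups, c("control", "case"))
  idx_case <- which(g == "case")
  n <- ncol(V); n1 <- length(idx_case)
  p <- nrow(V)

  obs_w1 <- matrix(0, n, 1); obs_w1[idx_case, 1] <- 1
  obs_w0 <- matrix(1, n, 1) - obs_w1
  d_obs <- as.vector(.d_from_stats(.group_stats_multi(V, obs_w1, obs_w0),
                                   alpha1, alpha2))

  total_distinct <- choose(n, n1)
  exhaustive <- is.finite(total_distinct) && total_distinct <= params$n_permutations
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(params$seed + 1L)
  if (exhaustive) {
    warning("fewer distinct permutations (", total_distinct,
            ") than requested; enumerating all of them")
    combos <- utils::combn(n, n1)
    B <- ncol(combos)
    W1 <- matrix(0, n, B)
    W1[cbind(as.vector(combos), rep(seq_len(B), each = n1))] <- 1
  } else {
    B <- params$n_permutations
    W1 <- matrix(0, n, B)
    for (b in seq_len(B)) W1[sample(n, n1), b] <- 1
  }
  W0 <- 1 - W1
  Dperm <- .d_from_stats(.group_stats_multi(V, W1, W0), alpha1, alpha2)

  pooled <- sort(as.vector(Dperm))
  # count of permuted d >= observed d via position in the sorted pool
  n_ge <- length(pooled) - findInterval(d_obs, pooled, left.open = TRUE)
  p_value <- (1 + n_ge) / (1 + length(pooled))

  rank_obs <- rank(-d_obs, ties.method = "max")
  exceed <- matrix(0, p, B)
  for (b in seq_len(B)) {
    sb <- sort(Dperm[, b])
    exceed[, b] <- p - findInterval(d_obs, sb, left.open = TRUE)
  }
  fdr <- apply(exceed, 1, stats::median) / rank_obs
  fdr <- pmin(pmax(fdr, 0), 1)
  ord <- order(-d_obs)
  fdr[ord] <- rev(cummin(rev(fdr[ord])))

  tibble::tibble(protein = rownames(V) %||% as.character(seq_len(p)),
                 d = d_obs, p_value = p_value, fdr = fdr)
}

#' Per-protein log2 fold change (case minus control)
#'
#' Computed on present values of a log2-scale matrix; negative values mean
#' lower abundance in cases.
#'
#' @inheritParams rots_optimize
#' @return A tibble (`protein`, `log2_fc`).
#' @export
log2_fold_change <- function(x, groups = NULL) {
  V <- if (inherits(x, "lfq_matrix")) x$values else x
  if (inherits(x, "lfq_matrix")) stopifnot(x$scale == "log2")
  g <- if (is.null(groups)) sample_groups(x) else factor(groups, c("control", "case"))
  m_case <- rowMeans(V[, g == "case", drop = FALSE], na.rm = TRUE)
  m_ctrl <- rowMeans(V[, g == "control", drop = FALSE], na.rm = TRUE)
  tibble::tibble(protein = rownames(V) %||% as.character(seq_len(nrow(V))),
                 log2_fc = unname(m_case - m_ctrl))
}

#' Differential-abundance table
#'
#' Full chain: reproducibility optimization, permutation test at the selected
#' regularization, log2 fold changes; sorted by p-value ascending.
#'
#' @inheritParams rots_optimize
#' @return A tibble of class `diff_table` with columns `protein`, `log2_fc`,
#'   `d`, `p_value`, `fdr`, sorted by `p_value`; the selected
#'   (alpha1, alpha2, k) is stored in the `"rots_fit"` attribute.
#' @export
differential_table <- function(x, params = rots_params(), groups = NULL) {
  fit <- rots_optimize(x, params, groups = groups)
  res <- rots_permutation_test(x, fit$alpha1, fit$alpha2, params, groups = groups)
  fc <- log2_fold_change(x, groups = groups)
  out <- res |>
    dplyr::left_join(fc, by = "protein") |>
    dplyr::relocate("log2_fc", .after = "protein") |>
    dplyr::arrange(.data$p_value, dplyr::desc(.data$d))
  attr(out, "rots_fit") <- fit[c("alpha1", "alpha2", "k", "z")]
  class(out) <- c("diff_table", class(out))
  out
}

#' Significance views of a differential table
#'
#' @param results a `diff_table`.
#' @param p,fdr thresholds for the two conventional views.
#' @return A named list of two tibbles: proteins with `p_value < p` and with
#'   `fdr < fdr`.
#' @export
significant_proteins <- function(results, p = 0.05, fdr = 0.05) {
  p_thr <- p; fdr_thr <- fdr
  list(nominal = dplyr::filter(results, .data$p_value < p_thr),
       fdr = dplyr::filter(results, .data$fdr < fdr_thr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
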