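#' Panel-selection configuration
#'
#' Controls the repeated cross-validated L1-penalized logistic selection and
#' the forward AUROC search over the most frequently selected candidates.
#'
#' @param n_repeats number of random fold-assignment repeats.
#' @param n_folds number of cross-validation folds (pairs never split).
#' @param prescreen_p_threshold within-fold differential-abundance p-value
#'   cutoff for a protein to enter the Lasso.
#' @param n_top_candidates number of most frequently selected proteins kept
#'   as panel candidates.
#' @param ci_level confidence level for AUROC intervals.
#' @param improvement_p_threshold a candidate is added to the panel only
#'   while its addition improves AUROC with a DeLong p below this.
#' @param inner_nfolds folds of the inner cross-validation that picks the
#'   Lasso penalty on each training portion.
#' @param global_prescreen if `TRUE`, prescreen once on the full data
#'   instead of per training fold (sensitivity toggle; default `FALSE`).
#' @param seed integer seed.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(n_repeats = 200L, n_folds = 3L,
                         prescreen_p_threshold = 0.05,
                         n_top_candidates = 20L, ci_level = 0.95,
                         improvement_p_threshold = 0.05,
                         inner_nfolds = 5L, global_prescreen = FALSE,
                         seed = 1L) {
  stopifnot(n_folds >= 2, prescreen_p_threshold > 0, prescreen_p_threshold < 1,
            improvement_p_threshold > 0, improvement_p_threshold < 1,
            ci_level > 0, ci_level < 1)
  structure(list(
    n_repeats = as.integer(n_repeats), n_folds = as.integer(n_folds),
    prescreen_p_threshold = prescreen_p_threshold,
    n_top_candidates = as.integer(n_top_candidates), ci_level = ci_level,
    improvement_p_threshold = improvement_p_threshold,
    inner_nfolds = as.integer(inner_nfolds),
    global_prescreen = isTRUE(global_prescreen), seed = as.integer(seed)
  ), class = "panel_config")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random case scores above a random control, ties
#' counted one half.
#'
#' @param scores numeric vector of per-subject scores.
#' @param labels binary labels (logical, 0/1, or `"case"`/`"control"`); the
#'   higher/`case` level is the positive class.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- .as_binary_labels(labels)
  m <- sum(y == 1); n <- sum(y == 0)
  if (m == 0 || n == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)
}

.as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("case", "control"))
    if (length(bad) > 0) stop("unknown labels: ", paste(bad, collapse = ", "),
                              call. = FALSE)
    as.integer(labels == "case")
  } else {
    as.integer(as.logical(labels))
  }
}

# placement values: for each case, the fraction of controls it beats
# (ties half), and vice versa; both vectors have mean equal to the AUC
.placements <- function(scores, y) {
  cases <- scores[y == 1]; controls <- scores[y == 0]
  psi <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi), auc = mean(psi))
}

#' DeLong variance, confidence interval and paired AUROC comparison
#'
#' Nonparametric (placement-value / structural-components) estimate of the
#' AUROC sampling variance, a Wald confidence interval clipped to \[0, 1\],
#' and the paired two-classifier comparison on the same subjects.
#'
#' @param scores,scores_a,scores_b per-subject score vectors (same subjects
#'   for a paired comparison).
#' @param labels binary labels as in [auroc()].
#' @param level confidence level.
#' @return `delong_ci()`: a list with `auc`, `se`, `low`, `high`.
#'   `delong_test()`: a list with `auc_a`, `auc_b`, `se_diff`, `z`,
#'   `p_value` (two-sided normal).
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  y <- .as_binary_labels(labels)
  pl <- .placements(scores, y)
  v <- stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
  se <- sqrt(v)
  zq <- stats::qnorm((1 + level) / 2)
  list(auc = pl$auc, se = se,
       low = max(0, pl$auc - zq * se), high = min(1, pl$auc + zq * se))
}

#' @rdname delong_ci
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- .as_binary_labels(labels)
  stopifnot(length(scores_a) == length(scores_b))
  pa <- .placements(scores_a, y); pb <- .placements(scores_b, y)
  m <- sum(y == 1); n <- sum(y == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_diff <= 0) {
    if (isTRUE(all.equal(pa$auc, pb$auc))) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, se_diff = 0, z = 0, p_value = 1))
    }
    stop("zero variance of the AUROC difference with unequal AUROCs",
         call. = FALSE)
  }
  se <- sqrt(var_diff)
  z <- (pa$auc - pb$auc) / se
  list(auc_a = pa$auc, auc_b = pb$auc, se_diff = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Fast Welch-test prescreen
#'
#' Row-wise two-sided Welch t-test p-values; the default `diff_tester` used
#' inside each training fold of [lasso_stability()]. (A full
#' reproducibility-optimized permutation refit per fold is available by
#' passing [rots_prescreen()] instead, at considerable cost.)
#'
#' @param values proteins x subjects numeric matrix.
#' @param groups `"case"`/`"control"` per column.
#' @return Numeric vector of p-values, one per row.
#' @export
prescreen_welch <- function(values, groups) {
  y <- .as_binary_labels(groups)
  v1 <- values[, y == 1, drop = FALSE]; v0 <- values[, y == 0, drop = FALSE]
  n1 <- ncol(v1); n0 <- ncol(v0)
  m1 <- rowMeans(v1); m0 <- rowMeans(v0)
  s1 <- rowSums((v1 - m1)^2) / (n1 - 1); s0 <- rowSums((v0 - m0)^2) / (n0 - 1)
  se2 <- s1 / n1 + s0 / n0
  tt <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[!is.finite(p)] <- 1
  p
}

#' Permutation-test prescreen
#'
#' A `diff_tester` for [lasso_stability()] that refits the
#' reproducibility-optimized permutation test on each training portion.
#'
#' @param n_permutations,n_bootstrap scaled-down defaults for per-fold use.
#' @return A function `(values, groups) -> p-values`.
#' @export
rots_prescreen <- function(n_permutations = 200L, n_bootstrap = 100L) {
  function(values, groups) {
    params <- rots_params(n_permutations = n_permutations,
                          n_bootstrap = n_bootstrap,
                          top_list_sizes = c(10L, 25L, 50L), seed = 1L)
    fit <- rots_optimize(values, params, groups = groups)
    rots_permutation_test(values, fit$alpha1, fit$alpha2, params,
                          groups = groups)$p_value
  }
}

# pair-preserving fold assignment: returns fold id per subject column
.pair_folds <- function(pair_id, n_folds) {
  pairs <- unique(pair_id)
  fold_of_pair <- sample(rep(seq_len(n_folds), length.out = length(pairs)))
  names(fold_of_pair) <- pairs
  unname(fold_of_pair[pair_id])
}

#' Selection frequencies by repeated cross-validated Lasso
#'
#' For each of `n_repeats` random fold assignments (matched pairs kept
#' intact within folds) and each fold: proteins passing the within-fold
#' differential prescreen enter an L1-penalized logistic regression fit on
#' the standardized training portion, with the penalty chosen by inner
#' cross-validated deviance; proteins with nonzero coefficients at that
#' penalty count as selected. The selection frequency is
#' selections / (n_repeats * n_folds).
#'
#' @param x a subject-level [lfq_matrix()] with `group` and `pair_id` in its
#'   sample metadata.
#' @param cfg a [panel_config()].
#' @param diff_tester function `(values, groups) -> p-values` used for the
#'   prescreen; default [prescreen_welch()].
#' @return A tibble (`protein`, `n_selected`, `frequency`) sorted by
#'   decreasing frequency; skipped folds are reported in the
#'   `"stability_log"` attribute.
#' @export
lasso_stability <- function(x, cfg = panel_config(),
                            diff_tester = prescreen_welch) {
  stopifnot(inherits(x, "lfq_matrix"),
            all(c("group", "pair_id") %in% names(x$samples)))
  V <- x$values
  g <- as.character(x$samples$group)
  pair <- x$samples$pair_id
  p <- nrow(V)
  counts <- stats::setNames(integer(p), rownames(V))
  n_empty_prescreen <- 0L

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$seed)
  global_p <- if (cfg$global_prescreen) diff_tester(V, g) else NULL

  for (rep_i in seq_len(cfg$n_repeats)) {
    folds <- .pair_folds(pair, cfg$n_folds)
    for (f in seq_len(cfg$n_folds)) {
      train <- folds != f
      if (length(unique(g[train])) < 2) next  # cannot happen with intact pairs
      pvals <- if (cfg$global_prescreen) global_p else
        diff_tester(V[, train, drop = FALSE], g[train])
      keep <- which(pvals < cfg$prescreen_p_threshold)
      if (length(keep) == 0) {
        n_empty_prescreen <- n_empty_prescreen + 1L
        next
      }
      if (length(keep) == 1) {
        # glmnet needs >= 2 predictors; a single survivor is selected as-is
        counts[keep] <- counts[keep] + 1L
        next
      }
      xtr <- t(V[keep, train, drop = FALSE])
      ytr <- as.integer(g[train] == "case")
      foldid <- .pair_folds(pair[train], min(cfg$inner_nfolds, sum(train)))
      cvfit <- suppressWarnings(
        glmnet::cv.glmnet(xtr, ytr, family = "binomial",
                          foldid = foldid, standardize = TRUE,
                          type.measure = "deviance"))
      beta <- as.vector(stats::coef(cvfit, s = "lambda.min"))[-1]
      counts[keep[beta != 0]] <- counts[keep[beta != 0]] + 1L
    }
  }
  out <- tibble::tibble(protein = names(counts), n_selected = unname(counts),
                        frequency = unname(counts) / (cfg$n_repeats * cfg$n_folds)) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$protein)
  attr(out, "stability_log") <- list(n_empty_prescreen = n_empty_prescreen,
                                     n_fits = cfg$n_repeats * cfg$n_folds)
  out
}

# leave-pair-out cross-validated predicted probabilities of an unpenalized
# logistic model on the given predictor rows; deterministic (no RNG)
.cv_logistic_scores <- function(V, proteins, y, pair) {
  X <- cbind(1, t(V[proteins, , drop = FALSE]))
  scores <- numeric(length(y))
  for (pr in unique(pair)) {
    hold <- pair == pr
    fit <- suppressWarnings(
      stats::glm.fit(X[!hold, , drop = FALSE], y[!hold],
                     family = stats::binomial())
    )
    eta <- X[hold, , drop = FALSE] %*% fit$coefficients
    scores[hold] <- as.vector(eta)
  }
  scores
}

#' Select the final biomarker panel by forward AUROC search
#'
#' Candidates are the `n_top_candidates` most frequently selected proteins
#' (ties broken by smaller differential p-value, then lexicographically).
#' Starting from the top candidate, the search greedily adds the candidate
#' giving the largest cross-validated AUROC of an unpenalized logistic
#' model (scored by leave-pair-out predicted probabilities) and stops at the
#' first addition that does not significantly improve AUROC (DeLong p >=
#' `improvement_p_threshold`, or no AUROC increase) — guaranteeing the
#' smallest panel among those with significant step-wise gains.
#'
#' @param frequencies tibble from [lasso_stability()].
#' @param x the subject-level [lfq_matrix()] used for scoring.
#' @param cfg a [panel_config()].
#' @param diff optional `diff_table` used for frequency tie-breaking.
#' @return An object of class `panel_fit`: the panel, candidates,
#'   frequencies, per-step trace, cross-validated and apparent panel AUROCs
#'   with DeLong confidence intervals, the single-top-candidate AUROC, and
#'   the panel-vs-single DeLong comparison p-value.
#' @export
select_panel <- function(frequencies, x, cfg = panel_config(), diff = NULL) {
  stopifnot(inherits(x, "lfq_matrix"))
  freq <- dplyr::filter(frequencies, .data$n_selected > 0)
  if (nrow(freq) == 0) {
    stop("no candidates: no protein was ever selected", call. = FALSE)
  }
  if (!is.null(diff)) {
    freq <- dplyr::left_join(freq,
      dplyr::select(diff, "protein", diff_p = "p_value"), by = "protein")
  } else {
    freq$diff_p <- NA_real_
  }
  freq <- dplyr::arrange(freq, dplyr::desc(.data$frequency), .data$diff_p,
                         .data$protein)
  candidates <- utils::head(freq$protein, cfg$n_top_candidates)

  y <- .as_binary_labels(x$samples$group)
  pair <- x$samples$pair_id
  V <- x$values

  panel <- candidates[1]
  scores <- .cv_logistic_scores(V, panel, y, pair)
  auc_now <- auroc(scores, y)
  trace <- list(tibble::tibble(step = 1L, added = panel, panel_size = 1L,
                               auroc = auc_now, delong_p = NA_real_))
  single_scores <- scores
  repeat {
    remaining <- setdiff(candidates, panel)
    if (length(remaining) == 0) break
    step_auc <- vapply(remaining, function(cand) {
      auroc(.cv_logistic_scores(V, c(panel, cand), y, pair), y)
    }, numeric(1))
    best <- remaining[which.max(step_auc)]
    new_scores <- .cv_logistic_scores(V, c(panel, best), y, pair)
    cmp <- delong_test(new_scores, scores, y)
    improved <- cmp$auc_a > cmp$auc_b && cmp$p_value < cfg$improvement_p_threshold
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(trace) + 1L, added = best,
      panel_size = length(panel) + if (improved) 1L else 0L,
      auroc = cmp$auc_a, delong_p = cmp$p_value)
    if (!improved) break
    panel <- c(panel, best)
    scores <- new_scores
  }

  ci_single <- delong_ci(single_scores, y, cfg$ci_level)
  ci_panel <- delong_ci(scores, y, cfg$ci_level)
  comparison_p <- if (length(panel) > 1) delong_test(scores, single_scores, y)$p_value
    else NA_real_

  # apparent (full-data fit) AUROC for the final panel
  full_fit <- suppressWarnings(stats::glm.fit(
    cbind(1, t(V[panel, , drop = FALSE])), y, family = stats::binomial()))
  apparent_scores <- as.vector(cbind(1, t(V[panel, , drop = FALSE])) %*%
                                 full_fit$coefficients)
  ci_apparent <- delong_ci(apparent_scores, y, cfg$ci_level)

  structure(list(
    panel = panel, candidates = candidates,
    frequencies = stats::setNames(freq$frequency, freq$protein),
    trace = dplyr::bind_rows(trace),
    auroc_single = ci_single, auroc_panel = ci_panel,
    auroc_panel_apparent = ci_apparent, comparison_p = comparison_p,
    cv_scores = scores, single_scores = single_scores,
    apparent_scores = apparent_scores, labels = y, ci_level = cfg$ci_level
  ), class = "panel_fit")
}

#' @export
print.panel_fit <- function(x, ...) {
  cat("<panel_fit>\n  panel:", paste(x$panel, collapse = " + "), "\n")
  cat(sprintf("  AUROC (cross-validated): %.2f (%d%% CI %.2f-%.2f)\n",
              x$auroc_panel$auc, round(100 * x$ci_level),
              x$auroc_panel$low, x$auroc_panel$high))
  cat(sprintf("  AUROC (apparent):        %.2f (%d%% CI %.2f-%.2f)\n",
              x$auroc_panel_apparent$auc, round(100 * x$ci_level),
              x$auroc_panel_apparent$low, x$auroc_panel_apparent$high))
  cat(sprintf("  top candidate alone:     %.2f (%d%% CI %.2f-%.2f)\n",
              x$auroc_single$auc, round(100 * x$ci_level),
              x$auroc_single$low, x$auroc_single$high))
  if (!is.na(x$comparison_p)) {
    cat(sprintf("  panel vs single DeLong p = %.3g\n", x$comparison_p))
  }
  invisible(x)
}
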