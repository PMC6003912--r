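#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a panel fit
#'
#' @param x a `panel_fit` from [select_panel()].
#' @param ... unused.
#' @return One row per candidate protein: selection frequency, whether it
#'   entered the final panel, and the forward-search step at which it was
#'   added (NA if never).
#' @method tidy panel_fit
#' @export
tidy.panel_fit <- function(x, ...) {
  added <- x$trace |>
    dplyr::filter(.data$panel_size == .data$step) |>
    dplyr::select(protein = "added", "step")
  tibble::tibble(protein = x$candidates,
                 frequency = unname(x$frequencies[x$candidates]),
                 in_panel = x$candidates %in% x$panel) |>
    dplyr::left_join(added, by = "protein")
}

#' @rdname tidy.panel_fit
#' @return `glance()`: a one-row tibble with panel size, cross-validated and
#'   apparent panel AUROCs with CI bounds, the single-marker AUROC, and the
#'   panel-vs-single DeLong p-value.
#' @method glance panel_fit
#' @export
glance.panel_fit <- function(x, ...) {
  tibble::tibble(
    panel_size = length(x$panel),
    auroc_single = x$auroc_single$auc,
    auroc_single_low = x$auroc_single$low, auroc_single_high = x$auroc_single$high,
    auroc_panel_cv = x$auroc_panel$auc,
    auroc_panel_cv_low = x$auroc_panel$low, auroc_panel_cv_high = x$auroc_panel$high,
    auroc_panel_apparent = x$auroc_panel_apparent$auc,
    comparison_p = x$comparison_p
  )
}

#' Tidy a discovery run
#'
#' @param x a `discovery_run` from [run_discovery()].
#' @param ... unused.
#' @return The differential-abundance tibble.
#' @method tidy discovery_run
#' @export
tidy.discovery_run <- function(x, ...) tibble::as_tibble(x$diff)

#' @rdname tidy.discovery_run
#' @method glance discovery_run
#' @export
glance.discovery_run <- function(x, ...) {
  tibble::tibble(
    n_input_rows = x$manifest$n_input_rows,
    n_retained = x$manifest$n_retained,
    n_subjects = x$manifest$n_subjects,
    n_p05 = sum(x$diff$p_value < 0.05),
    n_fdr05 = sum(x$diff$fdr < 0.05),
    panel_size = if (is.null(x$panel)) 0L else length(x$panel$panel)
  )
}
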