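#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the outer-fold predictions of a classification run
#'
#' @param x A `repertoire_classification` object from [nested_loocv()].
#' @param ... Unused.
#' @return A tibble with one row per outer fold: held-out sample, truth,
#'   prediction, chosen hyperparameters and number of selected alpha values.
#' @export
tidy.repertoire_classification <- function(x, ...) {
  x$predictions
}

#' One-row performance summary of a classification run
#'
#' @param x A `repertoire_classification` object.
#' @param ... Unused.
#' @return A one-row tibble with `bacc`, `sensitivity`, `specificity` (all in
#'   percent), `median_n_alphas`, `n`, and — when a [permutation_test()] was
#'   run — `permutation_p` and `significant`.
#' @export
glance.repertoire_classification <- function(x, ...) {
  out <- tibble::tibble(
    bacc = x$bacc, sensitivity = x$sensitivity,
    specificity = x$specificity,
    median_n_alphas = x$median_n_alphas, n = x$n
  )
  if (!is.null(x$permutation_p)) {
    out$permutation_p <- x$permutation_p
    out$significant <- x$significant
  }
  out
}

#' Tidy an intersection report
#'
#' @param x An `intersection_report` from [detect_intersection()].
#' @param ... Unused.
#' @return A tibble with one row per profile crossing (zero rows when the
#'   profiles do not intersect).
#' @export
tidy.intersection_report <- function(x, ...) {
  tibble::tibble(crossing_alpha = x$crossing_alphas)
}

#' Tidy a sub-repertoire delineation
#'
#' @param x A `subrepertoire_delineation` from [cumulative_curves()].
#' @param ... Unused.
#' @return The per-rank cumulative-curve tibble.
#' @export
tidy.subrepertoire_delineation <- function(x, ...) {
  x$curves
}
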