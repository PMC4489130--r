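#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot diversity or evenness profiles
#'
#' @param object A profile tibble (class `divprof_profile`) from
#'   [repertoire_profiles()], [diversity_profile()] or [evenness_profile()].
#' @param feature Which profile to draw when both are present.
#' @param ... Unused.
#' @return A ggplot: profile value against alpha, one curve per sample.
#' @export
autoplot.divprof_profile <- function(object,
                                     feature = c("diversity", "evenness"),
                                     ...) {
  feature <- intersect(match.arg(feature, several.ok = TRUE), names(object))[1]
  if (is.na(feature)) abort("No diversity or evenness column to plot.")
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$alpha, y = .data[[feature]], colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(alpha), y = feature, colour = "sample") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.divprof_profile
#' @param profiles Profile tibble.
#' @export
plot_profiles <- function(profiles, feature = c("diversity", "evenness")) {
  autoplot(new_profile_tbl(profiles), feature)
}

#' Plot rank-ordered cumulative frequency curves
#'
#' Visualizes the sub-repertoire delineation of two repertoires: the regions
#' where each cumulative curve lies above the other are the differentially
#' expanded sub-repertoires.
#'
#' @param object A `subrepertoire_delineation` from [cumulative_curves()].
#' @param ... Unused.
#' @return A ggplot of both cumulative curves against clonal rank.
#' @export
autoplot.subrepertoire_delineation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curves,
                              c("cumulative_1", "cumulative_2"),
                              names_to = "repertoire", names_prefix = "cumulative_",
                              values_to = "cumulative_frequency")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$rank, y = .data$cumulative_frequency,
    colour = .data$repertoire)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "clonal rank", y = "cumulative frequency") +
    ggplot2::theme_minimal()
}

#' Plot a depth-robustness summary
#'
#' @param object A `divprof_robustness` tibble from [robustness_analysis()].
#' @param ... Unused.
#' @return A ggplot with the intersection-change probability and the mean
#'   profile distance against sequencing depth fraction.
#' @export
autoplot.divprof_robustness <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("intersection_change_probability", "mean_profile_distance"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sequencing depth fraction") +
    ggplot2::theme_minimal()
}

#' Plot a dendrogram-fidelity sweep
#'
#' @param object A `divprof_sweep` tibble from [alpha_sweep()].
#' @param ... Unused.
#' @return A ggplot of the cophenetic correlation against the number of alpha
#'   values used.
#' @export
autoplot.divprof_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_alphas,
                                       y = .data$cophenetic_r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of alpha values",
                  y = "cophenetic correlation r") +
    ggplot2::theme_minimal()
}
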