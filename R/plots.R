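#' 2D discrimination plot of cohort delta means
#'
#' Case mean against control mean for every reference pair, with the
#' diagonal of non-discriminating pairs and the band of pairs whose means
#' are too close to zero to be considered.
#'
#' @param object an `nps_delta_means` tibble.
#' @param min_abs band half-width shown (default 0.5).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.nps_delta_means <- function(object, min_abs = 0.5, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$control_mean, y = .data$case_mean)) +
    ggplot2::annotate("rect", xmin = -min_abs, xmax = min_abs,
                      ymin = -min_abs, ymax = min_abs,
                      alpha = 0.15, fill = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$diag_distance)) +
    ggplot2::scale_colour_viridis_c(name = "distance\nfrom diagonal") +
    ggplot2::labs(x = "control mean Δ", y = "case mean Δ",
                  title = "Cohort discrimination by pairwise distance differences") +
    ggplot2::theme_minimal()
}

#' Heatmap of a per-cohort 2D delta histogram
#'
#' @param histogram output of [delta_histogram()].
#' @return A ggplot object, faceted by cohort.
#' @export
plot_delta_histogram <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$dx, y = .data$dy, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~cohort) +
    ggplot2::scale_fill_viridis_c(name = "subjects") +
    ggplot2::labs(x = "Δ (pair x)", y = "Δ (pair y)") +
    ggplot2::theme_minimal()
}

#' Threshold-scan profile plot
#'
#' Number of significant reference pairs as a function of the survival
#' threshold, with the chosen optimum marked.
#'
#' @param object an `nps_scan` result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.nps_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(x = .data$threshold, y = .data$n_significant)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$best_threshold,
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "survival threshold [days]",
                  y = "significant reference pairs",
                  title = paste0("Optimal threshold: ", object$best_threshold,
                                 " days")) +
    ggplot2::theme_minimal()
}

#' Reference-profile frequency plot
#'
#' Multiplicity spectrum of a decomposition, labelled with haplotype
#' strings where available.
#'
#' @param object an `nps_decomposition`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.nps_decomposition <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$label <- ifelse(is.na(d$haplotype), d$pattern, d$haplotype)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label, -.data$frequency),
                                  y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "frequency",
                  title = "Reference cycle frequencies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
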