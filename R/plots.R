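# ggplot2 displays for fitted objects and evaluation tables.

#' Plot posterior inclusion probabilities along the locus
#'
#' @param object A `finemap_fit`.
#' @param ... Unused.
#' @return A ggplot: PIP against position, credible-set members coloured by
#'   set.
#' @method autoplot finemap_fit
#' @export
autoplot.finemap_fit <- function(object, ...) {
  td <- tidy(object)
  td$set <- factor(td$cs)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$pos, y = .data$pip)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$set), size = 1.6) +
    ggplot2::scale_colour_discrete(na.value = "grey60",
                                   name = "credible set") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (bp)", y = "PIP") +
    ggplot2::theme_minimal()
}

#' Calibration plot (expected vs observed precision per PIP bin)
#'
#' @param calib Tibble from [calibration()].
#' @return A ggplot.
#' @export
plot_calibration <- function(calib) {
  ggplot2::ggplot(calib, ggplot2::aes(x = .data$expected,
                                      y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$count)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "expected precision (mean PIP)",
                  y = "observed precision") +
    ggplot2::theme_minimal()
}

#' Enrichment-weight forest plot
#'
#' @param object An `enrichment_model` from [estimate_weights()].
#' @param ... Unused.
#' @return A ggplot of weights with 95% confidence intervals; selected
#'   annotations are highlighted.
#' @method autoplot enrichment_model
#' @export
autoplot.enrichment_model <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$weight,
                                       y = .data$annotation)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::labs(x = "enrichment weight (log fold)", y = NULL,
                  colour = "G-test selected") +
    ggplot2::theme_minimal()
}
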