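# ggplot2 front-ends for the main result types.

#' Plot an anchored metaplot
#'
#' Smoothed co-oriented (F) and opposite (R) strand densities against the
#' offset from the anchor.
#'
#' @param object a [anchored_profile()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.metaplot <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("offset", "F", "R")],
    cols = c("F", "R"), names_to = "orientation", values_to = "density")
  ggplot2::ggplot(df, ggplot2::aes(.data$offset / 1000, .data$density,
                                   colour = .data$orientation)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(F = "#1b9e77", R = "grey55")) +
    ggplot2::labs(x = "offset from anchor (kb)", y = "smDNA density (RPKM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a normalized Chi metaplot with its background and drop
#'
#' @param object a [normalize_and_drop()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.chi_drop <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(.data$offset / 1000, .data$relative_density)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "#1b9e77") +
    ggplot2::annotate("text", x = 0, y = Inf, vjust = 1.5,
                      label = sprintf("drop %.1f%%", object$drop_percent)) +
    ggplot2::labs(x = "offset from Chi (kb)",
                  y = "relative smDNA density (background = 1)") +
    ggplot2::theme_minimal()
}

#' Plot a rolling strand-ratio profile
#'
#' @param profile a [strand_ratio_profile()] result.
#' @return a ggplot of the (ratio-of-ratios) profile along the chromosome.
#' @export
plot_strand_ratio <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$center / 1e6, .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "#7570b3") +
    ggplot2::labs(x = "chromosome position (Mb)",
                  y = "plus/minus strand ratio") +
    ggplot2::theme_minimal()
}

#' Plot per-class enrichment distributions
#'
#' @param object an `enrichment_result`.
#' @param ... unused.
#' @return a ggplot comparing per-site +Cfx/control enrichments by class.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(object$per_site,
                  ggplot2::aes(.data$class, .data$enrichment,
                               colour = .data$class)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1), colour = "black") +
    ggplot2::labs(x = NULL, y = "+Cfx / control relative density",
                  subtitle = sprintf("Welch t = %.2f, p = %.2g",
                                     object$t_statistic, object$p_value)) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
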