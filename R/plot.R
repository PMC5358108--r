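# Channel colours follow the reporters they emulate.
channel_cols <- c(CFP = "#00B7EB", GFP = "#2CA02C", RFP = "#D62728",
                  DAPI = "#7F7F7F", BF = "#BCBD22")

channel_scale <- function() {
  ggplot2::scale_colour_manual(values = channel_cols, drop = TRUE)
}

#' Plot a radial fluorescence profile
#'
#' @param object a `lam_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lam_profile <- function(object, ...) {
  chans <- profile_channels(object)
  long <- tidyr::pivot_longer(tibble::as_tibble(object), dplyr::all_of(chans),
                              names_to = "channel", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(.data$radial_px, .data$intensity,
                                     colour = .data$channel)) +
    ggplot2::geom_line() + channel_scale() +
    ggplot2::labs(x = "radial position (px, centre → periphery)",
                  y = "mean band intensity") +
    ggplot2::theme_minimal()
}

#' Plot a normalised fluorescence density profile
#'
#' @param object a `lam_nprofile`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lam_nprofile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$density,
                                       colour = .data$channel)) +
    ggplot2::geom_line() + channel_scale() +
    ggplot2::labs(x = "radial position (ru)", y = "fluorescence density (1/ru)") +
    ggplot2::theme_minimal()
}

#' Plot ECDF curves with the uniform-distribution diagonal
#'
#' The dotted diagonal marks a perfectly even distribution of
#' fluorescence from centre to periphery; curves left of it are centrally
#' enriched.
#'
#' @param object a `lam_ecdf`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lam_ecdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$F, colour = .data$channel)) +
    ggplot2::geom_abline(slope = 0.01, intercept = 0, linetype = "dotted",
                         colour = "grey40") +
    ggplot2::geom_line() + channel_scale() +
    ggplot2::labs(x = "radial position (ru)", y = "cumulative fluorescence") +
    ggplot2::theme_minimal()
}

#' Plot cohort mean profiles with shaded error band
#'
#' @param object a `lam_meanprofile` from [average_profiles()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lam_meanprofile <- function(object, ...) {
  ylab <- if (identical(attr(object, "value"), "F")) "cumulative fluorescence"
          else "fluorescence density (1/ru)"
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$mean,
                                       colour = .data$channel, fill = .data$channel)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$err,
                                      ymax = .data$mean + .data$err),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() + channel_scale() +
    ggplot2::scale_fill_manual(values = channel_cols) +
    ggplot2::labs(x = "radial position (ru)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @export
plot.lam_profile <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.lam_nprofile <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.lam_ecdf <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.lam_meanprofile <- function(x, ...) print(autoplot(x, ...))
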