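#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot sector loadings along the alignment
#'
#' Mode loadings per alignment column with the sector threshold marked;
#' sector members highlighted.
#'
#' @param object A `sector_definition`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sector_definition
#' @export
autoplot.sector_definition <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$column, y = .data$loading,
                                    colour = .data$in_sector)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey50"),
                                 name = "in sector") +
    ggplot2::labs(x = "alignment column",
                  y = paste0("mode ", object$mode, " loading"))
}

#' Plot a conservation profile
#'
#' @param profile Tibble from [conservation_profile()] or
#'   [kl_conservation()].
#' @return A ggplot of `D_i` per column.
#' @export
plot_conservation <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$column,
                                        y = .data$conservation)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::labs(x = "alignment column", y = "conservation D (nats)")
}

#' Scatter of sequences in correlation space
#'
#' @param coords Tibble from [project_sequences()] (optionally labeled via
#'   [annotate_projection()]).
#' @param modes Length-2 character vector of mode columns.
#' @return A ggplot.
#' @export
plot_projection <- function(coords, modes = c("mode1", "mode2")) {
  stopifnot(all(modes %in% names(coords)))
  aes <- if ("label" %in% names(coords)) {
    ggplot2::aes(x = .data[[modes[1]]], y = .data[[modes[2]]],
                 colour = .data$label)
  } else {
    ggplot2::aes(x = .data[[modes[1]]], y = .data[[modes[2]]])
  }
  ggplot2::ggplot(coords, aes) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = modes[1], y = modes[2])
}

#' Plot a damped-sine fit over its trace
#'
#' @param object A `damped_sine_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot damped_sine_fit
#' @export
autoplot.damped_sine_fit <- function(object, ...) {
  df <- tibble::tibble(time_h = object$trace$time_h,
                       counts = object$trace$counts,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$counts), size = 0.4,
                        colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#2166ac") +
    ggplot2::labs(x = "time (h)", y = "detrended counts",
                  subtitle = sprintf("T = %.2f h, goodness %.1f%% (%s)",
                                     object$period_h, object$goodness,
                                     if (object$rhythmic) "rhythmic"
                                     else "arrhythmic"))
}

#' Plot a one-phase-decay fit
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  df <- tibble::tibble(time_h = object$trace$time_h,
                       counts = object$trace$counts,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$counts), size = 0.4,
                        colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#b2182b") +
    ggplot2::labs(x = "time (h)", y = "normalized luminescence",
                  subtitle = sprintf("t1/2 = %.2f h", object$half_life_h))
}

#' Heat map of scaled traces
#'
#' @param scaled Matrix from [heatmap_scale()] (rows = traces).
#' @param time_h Optional time axis for the columns.
#' @return A ggplot tile map, values in \[-1, 1\].
#' @export
plot_trace_heatmap <- function(scaled, time_h = NULL) {
  if (is.null(time_h)) time_h <- seq_len(ncol(scaled))
  df <- tidyr::expand_grid(trace = seq_len(nrow(scaled)),
                           i = seq_len(ncol(scaled)))
  df$time_h <- time_h[df$i]
  df$value <- scaled[cbind(df$trace, df$i)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$trace,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "black", high = "#ffff33") +
    ggplot2::labs(x = "time (h)", y = "trace")
}
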