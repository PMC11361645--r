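#' Plot methods for traces, ladders, trajectories and image pairs
#'
#' ggplot2 `autoplot()` methods for the package's result types: raw
#' fluorescence traces (optionally overlaid with a fitted exponential), the
#' `k_obs`-versus-concentration regression, nucleotide-cycle trajectories,
#' hydrolysis time courses, and a red/green composite of a synthetic image
#' pair with its ground-truth centroids.
#'
#' @param object The object to plot.
#' @param fit Optional `exp_fit` overlaid as a curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-gtpasekin
NULL

#' @rdname autoplot-gtpasekin
#' @export
autoplot.fluor_trace <- function(object, fit = NULL, ...) {
  mode <- attr(object, "mode") %||% "trace"
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time_s, y = .data$signal_au)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)",
                  title = sprintf("Stopped-flow %s trace", mode))
  if (!is.null(fit) && isTRUE(fit$converged)) {
    t <- object$time_s
    yhat <- if (fit$model == "association") {
      fit$offset + fit$amplitude * (1 - exp(-fit$rate * t))
    } else {
      fit$offset + fit$amplitude * exp(-fit$rate * t)
    }
    p <- p + ggplot2::geom_line(
      data = tibble(time_s = t, signal_au = yhat),
      color = "firebrick", linewidth = 0.6)
  }
  p
}

#' @rdname autoplot-gtpasekin
#' @export
autoplot.kobs_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$protein_conc_uM, y = .data$kobs)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "grey40", linewidth = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "protein concentration (uM)",
                  y = expression(k[obs] ~ (s^-1)),
                  title = "Observed rate vs protein concentration")
}

#' @rdname autoplot-gtpasekin
#' @export
autoplot.cycle_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time_s",
                              names_to = "state", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$fraction,
                                     color = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "fraction of protein",
                  title = "Nucleotide-cycle relaxation")
}

#' @rdname autoplot-gtpasekin
#' @export
autoplot.hydrolysis_tc <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time_s,
                                    y = .data$gtp_fraction)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (s)", y = "GTP fraction",
                  title = "GTP hydrolysis time course")
  if (!is.null(fit) && is.finite(fit$rate)) {
    t <- seq(0, max(object$time_s), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble(time_s = t, gtp_fraction = exp(-fit$rate * t)),
      color = "firebrick")
  }
  p
}

#' @rdname autoplot-gtpasekin
#' @export
autoplot.image_pair <- function(object, ...) {
  as_long <- function(img, channel) {
    tibble(row = rep(seq_len(nrow(img)), ncol(img)),
           col = rep(seq_len(ncol(img)), each = nrow(img)),
           intensity = as.vector(img), channel = channel)
  }
  long <- dplyr::bind_rows(as_long(object$channel_a, "channel A"),
                           as_long(object$channel_b, "channel B"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Synthetic image pair (true coloc %.0f%%)",
                                  100 * object$true_coloc_fraction))
}
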