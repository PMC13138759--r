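#' Plot a macro vasomotion simulation
#'
#' Diameter time courses of the recorded segments (optionally a subset),
#' overlaid the way synchronized vasomotion is usually displayed.
#'
#' @param object A `vd_sim`.
#' @param segments Optional segment ids to display (default: up to 10
#'   recorded segments).
#' @param channel Trace channel to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vd_sim <- function(object, segments = NULL, channel = "D", ...) {
  ids <- segments %||% head(object$record_ids, 10)
  tr <- object$trace[object$trace$segment_id %in% ids, ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time, y = .data[[channel]],
                                   colour = .data$segment_id)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = if (channel == "D") "diameter (um)" else channel,
                  colour = "segment") +
    ggplot2::theme_minimal()
}

#' Plot a cellular PA simulation
#'
#' Range-normalised overlays of diameter, SMC potential, calcium and wall
#' stress for one segment, the standard view for reading off the delay
#' chain of the oscillation.
#'
#' @param object A `vd_cell_sim`.
#' @param segment_id Segment to display (default: first recorded).
#' @param normalize Range-normalise each channel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vd_cell_sim <- function(object, segment_id = NULL, normalize = TRUE,
                                 ...) {
  segment_id <- segment_id %||% object$record_ids[1]
  tr <- object$trace[object$trace$segment_id == segment_id, ]
  long <- tidyr::pivot_longer(tr[, c("time", "D", "V_smc", "Ca", "WS")],
                              -"time", names_to = "channel")
  if (normalize) {
    long <- dplyr::group_by(long, .data$channel)
    long <- dplyr::mutate(long, value = (.data$value - min(.data$value)) /
                            (max(.data$value) - min(.data$value) + 1e-12))
    long <- dplyr::ungroup(long)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = if (normalize) "range-normalised" else "value",
                  title = segment_id) +
    ggplot2::theme_minimal()
}

#' Plot an I-V curve from a virtual voltage clamp
#'
#' @param object A `vd_iv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vd_iv <- function(object, ...) {
  ggplot2::ggplot(object$iv, ggplot2::aes(x = .data$V, y = .data$I)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$rmp, linetype = 3) +
    ggplot2::labs(x = "membrane potential (mV)", y = "steady-state current (a.u.)",
                  title = sprintf("IP = %g mmHg, RMP = %.1f mV", object$ip,
                                  object$rmp)) +
    ggplot2::theme_minimal()
}

#' Plot a gamma-band drive
#'
#' @param object A `vd_gamma` (normalised/smoothed) tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vd_gamma <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("t", "gb_norm", "gb_s")], -"t",
                              names_to = "signal")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "normalised gamma-band power") +
    ggplot2::theme_minimal()
}

#' Plot a myogenic tone curve
#'
#' @param mt A [myography_mt()] tibble.
#' @return A ggplot object.
#' @export
plot_myogenic_tone <- function(mt) {
  ggplot2::ggplot(mt, ggplot2::aes(x = .data$IP_exvivo)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$D_passive, colour = "passive")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$D_active, colour = "active")) +
    ggplot2::labs(x = "ex-vivo IP (mmHg)", y = "diameter (um)", colour = NULL) +
    ggplot2::theme_minimal()
}
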