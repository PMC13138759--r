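#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation into its long trace
#'
#' @param x A `vd_sim` (macro) or `vd_cell_sim` (cellular) object.
#' @param ... Unused.
#' @return The long trace tibble.
#' @export
tidy.vd_sim <- function(x, ...) x$trace

#' One-row summary of a simulation
#'
#' Duration, boundary pressures, number of recorded segments and, for macro
#' runs, the median steady-window amplitude across recorded PA segments.
#'
#' @param x A `vd_sim`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.vd_sim <- function(x, ...) {
  out <- tibble(mode = x$mode, duration = x$duration, abnp = x$abnp,
                vbnp = x$vbnp, n_recorded = length(x$record_ids))
  if (!is.null(x$summary)) {
    pa <- x$summary[x$summary$class == "PA", ]
    out$median_amplitude_pct <- stats::median(pa$amplitude_pct)
  }
  out
}

#' @export
tidy.vd_hemo <- function(x, ...) x$segments

#' @export
glance.vd_hemo <- function(x, ...) {
  tibble(abnp = x$abnp, vbnp = x$vbnp,
         max_flow = max(abs(x$segments$Q)),
         n_segments = nrow(x$segments))
}

#' @export
tidy.vd_metrics <- function(x, ...) {
  tibble(amplitude_pct = x$amplitude_pct, dominant_freq = x$dominant_freq,
         damping_time = x$damping_time, mean = x$mean, n_peaks = x$n_peaks)
}

#' @export
glance.vd_metrics <- function(x, ...) tidy.vd_metrics(x)

#' @export
tidy.vd_delay_chain <- function(x, ...) {
  tibble(stage = c(names(x$lags), "dilation_total", "constriction_total",
                   "period"),
         seconds = c(unname(x$lags), x$dilation_total, x$constriction_total,
                     x$period))
}

#' @export
tidy.vd_onset <- function(x, ...) x$onsets

#' @export
glance.vd_onset <- function(x, ...) {
  tibble(speed_onset = x$speed_onset, speed_peak = x$speed_peak,
         speed_is_upper_bound = x$speed_is_upper_bound)
}

#' @export
tidy.vd_iv <- function(x, ...) x$iv

#' @export
glance.vd_iv <- function(x, ...) tibble(ip = x$ip, rmp = x$rmp, rmr = x$rmr)

#' @export
glance.vd_report <- function(x, ...) {
  tibble(segment_id = x$segment_id, amplitude_pct = x$amplitude_pct,
         dominant_freq = x$dominant_freq, damping_time = x$damping_time,
         mean_D = x$mean_D,
         MR_share = x$MR_share %||% NA_real_,
         PD_share = x$PD_share %||% NA_real_)
}
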