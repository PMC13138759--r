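#' Peak-to-trough amplitude, dominant frequency and damping time
#'
#' Computes, over an analysis window of a diameter trace: the peak-to-trough
#' amplitude as a percentage of the mean (`(max - min)/mean x 100`), the
#' dominant oscillation frequency (periodogram peak), and the damping time
#' (first time the cycle amplitude envelope falls below 10% of the first
#' cycle's amplitude; `NA` for sustained oscillations). Cycle amplitudes
#' use local extrema with prominence at least 1% of the mean.
#'
#' @param time,x Time (s) and signal vectors on a uniform grid.
#' @param window Optional `c(t_min, t_max)` analysis window.
#' @param min_cycles Minimum cycles required for a frequency estimate.
#' @return A list of class `vd_metrics`: `amplitude_pct`, `dominant_freq`
#'   (Hz), `damping_time` (s or `NA`), `mean` (signal mean), `n_peaks`.
#' @export
amplitude_and_frequency <- function(time, x, window = NULL, min_cycles = 3) {
  if (!is.null(window)) {
    keep <- time >= window[1] & time <= window[2]
    if (sum(keep) < 8) abort("Analysis window too short.")
    time <- time[keep]; x <- x[keep]
  }
  if (length(x) < 8) abort("Trace too short for metrics.")
  dt <- stats::median(diff(time))
  mu <- mean(x)
  amplitude_pct <- (max(x) - min(x)) / mu * 100

  pk <- .peaks(x, prominence = 0.01 * abs(mu))
  tr <- .peaks(-x, prominence = 0.01 * abs(mu))
  dominant_freq <- NA_real_
  if (length(pk) >= min_cycles) {
    xc <- x - mean(x)
    sp <- stats::spec.pgram(stats::ts(xc, deltat = dt), taper = 0,
                            detrend = TRUE, plot = FALSE)
    dominant_freq <- sp$freq[which.max(sp$spec)]
  }
  damping_time <- NA_real_
  if (length(pk) >= 2 && length(tr) >= 2) {
    # cycle amplitude envelope from successive peak-trough pairs
    ev_t <- time[pk]
    env <- purrr::map_dbl(seq_along(pk), function(i) {
      j <- tr[which.min(abs(time[tr] - time[pk[i]]))]
      abs(x[pk[i]] - x[j])
    })
    a0 <- env[1]
    below <- which(env < 0.1 * a0)
    if (length(below)) {
      damping_time <- ev_t[below[1]] - time[1]
    } else if (max(ev_t) < time[1] + 0.8 * diff(range(time))) {
      # cycles fell below the detection floor before the window ended
      damping_time <- max(ev_t) - time[1]
    }
  }
  structure(list(amplitude_pct = amplitude_pct, dominant_freq = dominant_freq,
                 damping_time = damping_time, mean = mu,
                 n_peaks = length(pk)),
            class = "vd_metrics")
}

# local maxima with a simple prominence filter
.peaks <- function(x, prominence = 0) {
  i <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(i) || prominence <= 0) return(i)
  keep <- vapply(i, function(k) {
    left <- min(x[max(1L, k - 200L):k])
    right <- min(x[k:min(length(x), k + 200L)])
    x[k] - max(left, right) >= prominence
  }, logical(1))
  i[keep]
}

#' @export
print.vd_metrics <- function(x, ...) {
  cat("<vd_metrics> amplitude", round(x$amplitude_pct, 1),
      "% of mean; f =", signif(x$dominant_freq, 3), "Hz; damping_time =",
      if (is.na(x$damping_time)) "none (sustained)" else round(x$damping_time, 1),
      "\n")
  invisible(x)
}

#' Vasomotion metrics of a simulated segment
#'
#' Data-frame-first wrapper of [amplitude_and_frequency()] operating on a
#' simulation trace (or any tibble with `time`, `segment_id` and `D`).
#'
#' @param trace A trace tibble or a `vd_sim` object.
#' @param segment_id Segment to analyse.
#' @param window Analysis window `c(t_min, t_max)`; defaults to the final
#'   200 s.
#' @return A `vd_metrics` list.
#' @export
vasomotion_metrics <- function(trace, segment_id, window = NULL) {
  if (inherits(trace, "vd_sim")) trace <- trace$trace
  tr <- trace[trace$segment_id == segment_id, ]
  if (!nrow(tr)) abort("Segment not found in trace.")
  window <- window %||% c(max(tr$time) - 200, max(tr$time))
  amplitude_and_frequency(tr$time, tr$D, window)
}

#' Myogenic / passive decomposition of oscillation amplitude
#'
#' Shares of the diameter oscillation amplitude carried by the
#' myogenic-response and passive-distension components: peak-to-trough of
#' each component over the window, divided by the peak-to-trough of the
#' total diameter, times 100.
#'
#' @param trace A macro-trace tibble (columns `time`, `segment_id`, `D`,
#'   `D_MR`, `D_PD`) or `vd_sim`.
#' @param segment_id Segment to analyse.
#' @param window Analysis window; defaults to the final 200 s.
#' @return A list `MR_share`, `PD_share` (percent), `amp_D`, `amp_MR`,
#'   `amp_PD` (um).
#' @export
decompose_mr_pd <- function(trace, segment_id, window = NULL) {
  if (inherits(trace, "vd_sim")) trace <- trace$trace
  tr <- trace[trace$segment_id == segment_id, ]
  if (!nrow(tr)) abort("Segment not found in trace.")
  window <- window %||% c(max(tr$time) - 200, max(tr$time))
  tr <- tr[tr$time >= window[1] & tr$time <= window[2], ]
  p2t <- function(y) diff(range(y))
  amp_d <- p2t(tr$D)
  if (amp_d < 1e-3 * mean(tr$D)) {
    abort("Trace is not oscillatory in the analysis window; cannot decompose.")
  }
  list(MR_share = p2t(tr$D_MR) / amp_d * 100,
       PD_share = p2t(tr$D_PD) / amp_d * 100,
       amp_D = amp_d, amp_MR = p2t(tr$D_MR), amp_PD = p2t(tr$D_PD))
}

# 4-parameter logistic fit of a rising transient; returns coef vector
.fit_sigmoid <- function(time, y) {
  d0 <- min(y); a <- max(y) - min(y)
  t0 <- time[which.min(abs(y - (d0 + a / 2)))]
  s <- max(diff(range(time)) / 10, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ d0 + a / (1 + exp(-(time - t0) / s)),
                      start = list(d0 = d0, a = a, t0 = t0, s = s),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    abort(sprintf("Sigmoid fit failed (residual trend too irregular): range %.3g-%.3g",
                  min(y), max(y)))
  }
  coef(fit)
}

#' Dilation onset times and propagation speed across depths
#'
#' Fits a four-parameter sigmoid to the rising diameter at each depth and
#' defines onset as the first time the fitted curve's derivative exceeds a
#' threshold fraction of its maximum slope. The propagation speed is the
#' (least-squares) depth-per-onset-time slope, with a peak-time variant
#' from the raw trace maxima. Identical onsets at different depths yield an
#' infinite speed, flagged as an upper bound.
#'
#' @param trace Tibble with `time`, `cortical_depth`, `D` (one rising
#'   transient per depth), e.g. a windowed `vd_cell_sim` trace.
#' @param threshold Fraction of the maximum fitted slope defining onset.
#' @return A list of class `vd_onset`: `onsets` (tibble `cortical_depth`,
#'   `onset`, `t_peak`), `speed_onset` and `speed_peak` (um/s, possibly
#'   `Inf`), `speed_is_upper_bound`.
#' @export
onset_and_propagation <- function(trace, threshold = 0.05) {
  depths <- sort(unique(trace$cortical_depth), decreasing = TRUE)
  if (length(depths) < 2) abort("Need transients at two or more depths.")
  rows <- purrr::map(depths, function(dp) {
    tr <- trace[trace$cortical_depth == dp, ]
    cf <- .fit_sigmoid(tr$time, tr$D)
    # logistic derivative p(1-p) a/s; threshold crossing below t0
    pstar <- (1 - sqrt(1 - 4 * threshold / 4)) / 2  # p(1-p) = threshold * 1/4
    onset <- cf[["t0"]] - cf[["s"]] * log((1 - pstar) / pstar)
    tibble(cortical_depth = dp, onset = onset,
           t_peak = tr$time[which.max(tr$D)])
  })
  on <- dplyr::bind_rows(rows)
  speed_of <- function(tt) {
    if (diff(range(tt)) < 1e-9) return(Inf)
    f <- stats::lm(tt ~ on$cortical_depth)
    1 / abs(coef(f)[[2]])
  }
  sp_on <- speed_of(on$onset)
  sp_pk <- speed_of(on$t_peak)
  structure(list(onsets = on, speed_onset = sp_on, speed_peak = sp_pk,
                 speed_is_upper_bound = !is.finite(sp_on)),
            class = "vd_onset")
}

#' Full metrics report for a simulation
#'
#' Combines amplitude/frequency/damping metrics with the myogenic/passive
#' decomposition (when the trace carries the macro components).
#'
#' @param sim A `vd_sim`.
#' @param segment_id Segment to analyse.
#' @param window Analysis window (default: final 200 s).
#' @return A list of class `vd_report`.
#' @export
metrics_report <- function(sim, segment_id, window = NULL) {
  m <- vasomotion_metrics(sim, segment_id, window)
  out <- list(segment_id = segment_id, amplitude_pct = m$amplitude_pct,
              dominant_freq = m$dominant_freq, damping_time = m$damping_time,
              mean_D = m$mean)
  if (all(c("D_MR", "D_PD") %in% names(sim$trace))) {
    dec <- tryCatch(decompose_mr_pd(sim, segment_id, window),
                    error = function(e) NULL)
    if (!is.null(dec)) {
      out$MR_share <- dec$MR_share
      out$PD_share <- dec$PD_share
    }
  }
  structure(out, class = "vd_report")
}
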