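#' Neurogenic stimulus protocol
#'
#' Describes an impulse or step release of vasoactive mediators: nitric
#' oxide (NO, arbitrary units), glutamate (AU), and extracellular potassium
#' around endothelial and smooth-muscle cells (mM above baseline). NO rises
#' instantaneously in segments deeper than `depth_ref`; above that depth the
#' rise propagates upward at `propagation_speed`, reproducing the
#' depth-dependent onset of stimulus-evoked dilation. After release, NO
#' decays exponentially with `decay_tau`; potassium and glutamate return to
#' baseline instantly when the stimulus ends.
#'
#' @param kind `"impulse"` (instant release at `t_on`) or `"step"` (held
#'   from `t_on` to `t_off`).
#' @param t_on,t_off Stimulus window (s); for impulses `t_off` is ignored.
#' @param NO,glutamate,K_ex_ec,K_ex_smc Peak mediator levels (AU, AU, mM
#'   increment, mM increment).
#' @param depth_ref Depth (um) below which NO rises instantly.
#' @param propagation_speed Upward propagation speed of the NO rise (um/s).
#' @param decay_tau NO/cGMP decay time constant (s).
#' @return A list of class `vd_protocol`.
#' @export
stimulus_protocol <- function(kind = c("impulse", "step"), t_on = 0,
                              t_off = t_on, NO = 0, glutamate = 0,
                              K_ex_ec = 0, K_ex_smc = 0, depth_ref = 600,
                              propagation_speed = 400, decay_tau = 5) {
  kind <- match.arg(kind)
  if (t_off < t_on) abort("`t_off` must not precede `t_on`.")
  if (any(c(NO, glutamate, K_ex_ec, K_ex_smc) < 0)) {
    abort("Mediator levels must be non-negative.")
  }
  structure(list(kind = kind, t_on = t_on, t_off = t_off,
                 levels = c(NO = NO, glutamate = glutamate,
                            K_ex_ec = K_ex_ec, K_ex_smc = K_ex_smc),
                 depth_ref = depth_ref,
                 propagation_speed = propagation_speed,
                 decay_tau = decay_tau),
            class = "vd_protocol")
}

#' Depth-dependent onset delay of the NO rise
#'
#' Zero for segments at or below `depth_ref`; shallower segments see the
#' rise after `(depth_ref - depth) / propagation_speed` seconds.
#'
#' @param depth Cortical depth (um).
#' @param protocol A [stimulus_protocol()].
#' @return Delay in seconds.
#' @export
no_onset_delay <- function(depth, protocol) {
  stopifnot(all(depth >= 0))
  pmax(0, (protocol$depth_ref - depth) / protocol$propagation_speed)
}

#' Mediator levels over time
#'
#' Evaluates the protocol at times `t` for a segment at `depth`. Impulse NO:
#' instant rise at `t_on + onset_delay(depth)` then exponential decay with
#' `decay_tau`. Step NO: held between onset and `t_off`, then exponential
#' decay. Potassium and glutamate follow the stimulus window with instant
#' return to baseline (zero).
#'
#' @param t Time(s), s.
#' @param protocol A [stimulus_protocol()].
#' @param depth Cortical depth (um) of the target segment.
#' @return A tibble `t`, `NO`, `glutamate`, `K_ex_ec`, `K_ex_smc`.
#' @export
mediator_time_course <- function(t, protocol, depth = protocol$depth_ref) {
  rise <- protocol$t_on + no_onset_delay(depth, protocol)
  lv <- protocol$levels
  if (protocol$kind == "impulse") {
    no <- ifelse(t < rise, 0, lv[["NO"]] * exp(-(t - rise) / protocol$decay_tau))
    # impulses carry K/glutamate as a brief 0.5 s bolus (matching ~0.5 s
    # optogenetic stimulation)
    box <- as.numeric(t >= rise & t < rise + 0.5)
  } else {
    off <- protocol$t_off + (rise - protocol$t_on)
    no <- ifelse(t < rise, 0,
                 ifelse(t <= off, lv[["NO"]],
                        lv[["NO"]] * exp(-(t - off) / protocol$decay_tau)))
    box <- as.numeric(t >= rise & t <= off)
  }
  tibble(t = t, NO = no,
         glutamate = lv[["glutamate"]] * box,
         K_ex_ec = lv[["K_ex_ec"]] * box,
         K_ex_smc = lv[["K_ex_smc"]] * box)
}

#' Synthetic gamma-band power envelope
#'
#' Generates a reproducible, band-limited (0.01-0.3 Hz) positive envelope
#' with occasional step-like transitions, emulating integrated gamma-band
#' power binned at 0.4 s and resampled to `dt`. A stand-in for in-vivo
#' recordings, which are not packaged; real two-column (time, power) CSVs
#' can be loaded with [read_gamma_csv()].
#'
#' @param duration Length (s).
#' @param dt Output sampling interval (s).
#' @param seed Integer seed; the same seed yields the identical series.
#' @return A tibble of class `vd_gamma_raw` with columns `t`, `gb`.
#' @export
synthetic_gamma <- function(duration, dt = 0.2, seed = 1L) {
  stopifnot(duration > 0, dt > 0)
  bin <- 0.4
  n <- max(16L, ceiling(duration / bin))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  # band-limited noise via FFT mask on the 0.4 s grid
  white <- stats::rnorm(n)
  f <- seq(0, 1 / bin, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, 1 / bin - f)  # two-sided frequency axis
  mask <- as.numeric(f >= 0.01 & f <= 0.3)
  z <- fft(white)
  slow <- Re(fft(z * mask, inverse = TRUE)) / n
  slow <- slow / stats::sd(slow)
  # occasional step-like transitions: smoothed random telegraph
  n_steps <- max(1L, round(duration / 60))
  tele <- numeric(n)
  at <- sort(sample.int(n, n_steps))
  lvl <- stats::runif(n_steps, -1, 1)
  cur <- 0
  ki <- 1L
  for (i in seq_len(n)) {
    if (ki <= n_steps && i >= at[ki]) { cur <- lvl[ki]; ki <- ki + 1L }
    tele[i] <- cur
  }
  tele <- stats::filter(tele, rep(1 / 5, 5), sides = 1)
  tele[is.na(tele)] <- 0
  env <- 1 + 0.45 * slow + 0.8 * as.numeric(tele)
  env <- pmax(env, 0)
  tb <- seq_len(n) * bin
  tout <- seq(dt, duration, by = dt)
  gb <- approx(tb, env, xout = tout, rule = 2)$y
  structure(tibble(t = tout, gb = gb), class = c("vd_gamma_raw", class(tibble())))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Load a gamma-band envelope from CSV
#'
#' Expects two columns, time (s) and power (arbitrary units), with or
#' without a header.
#'
#' @param path CSV path.
#' @return A tibble with columns `t`, `gb`.
#' @export
read_gamma_csv <- function(path) {
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (!is.numeric(df[[1]])) df <- utils::read.csv(path, header = TRUE)
  if (ncol(df) < 2) abort("Gamma-band CSV needs two columns: time_s, power.")
  structure(tibble(t = as.numeric(df[[1]]), gb = as.numeric(df[[2]])),
            class = c("vd_gamma_raw", class(tibble())))
}

#' Range-normalise and decay-smooth a gamma-band envelope
#'
#' `gb_norm` rescales the envelope to \[0, 1\]. `gb_s` tracks `gb_norm`
#' instantly on increases and relaxes exponentially with `tau_smooth` on
#' decreases, so `gb_s >= gb_norm` everywhere; it models the slow decay of
#' NO-mediated damping of the myogenic response (the default 5 s matches
#' the NO/cGMP degradation time constant).
#'
#' @param gamma A tibble with columns `t`, `gb` (see [synthetic_gamma()]).
#' @param tau_smooth Decay time constant (s).
#' @return A tibble of class `vd_gamma` with columns `t`, `gb`, `gb_norm`,
#'   `gb_s`, plus attribute `lag`.
#' @export
normalize_and_smooth <- function(gamma, tau_smooth = 5) {
  gb <- gamma$gb
  rng <- range(gb)
  if (diff(rng) <= 0) abort("Cannot range-normalise a constant signal.")
  gb_norm <- (gb - rng[1]) / diff(rng)
  dt <- stats::median(diff(gamma$t))
  decay <- exp(-dt / tau_smooth)
  gb_s <- numeric(length(gb_norm))
  prev <- gb_norm[1]
  for (i in seq_along(gb_norm)) {
    prev <- max(gb_norm[i], prev * decay)
    gb_s[i] <- prev
  }
  structure(tibble(t = gamma$t, gb = gb, gb_norm = gb_norm, gb_s = gb_s),
            class = c("vd_gamma", class(tibble())))
}

#' Astrocytic coupling parameters
#'
#' Astrocyte endfeet sense arteriolar constriction; when the smoothed
#' fractional constriction rate exceeds `constriction_rate_threshold`, a
#' transient potassium release transiently inhibits the myogenic response
#' (an additive pulse in the same units as the gamma-band inhibition term),
#' subject to a per-segment refractory period. The threshold and refractory
#' values are free parameters of the rule; see [astro_sensitivity_scan()].
#'
#' @param constriction_rate_threshold Fractional constriction rate
#'   triggering an event (per s).
#' @param k_release_pulse Myogenic-inhibition pulse amplitude (um
#'   equivalent).
#' @param pulse_duration Pulse length (s).
#' @param refractory Minimum time between events on one segment (s).
#' @param rate_smooth Time constant of the rate-smoothing filter (s).
#' @return A list of class `vd_astro_params`.
#' @export
astro_params <- function(constriction_rate_threshold = 0.02,
                         k_release_pulse = 6, pulse_duration = 2,
                         refractory = 10, rate_smooth = 1) {
  stopifnot(constriction_rate_threshold > 0, pulse_duration > 0,
            refractory >= pulse_duration, rate_smooth > 0)
  structure(list(constriction_rate_threshold = constriction_rate_threshold,
                 k_release_pulse = k_release_pulse,
                 pulse_duration = pulse_duration, refractory = refractory,
                 rate_smooth = rate_smooth),
            class = "vd_astro_params")
}

#' Astrocytic constriction-triggered events on a diameter history
#'
#' Offline version of the trigger rule used inside the simulator: smooths
#' the fractional diameter rate of change with a first-order filter and
#' fires an event whenever it crosses `-constriction_rate_threshold`
#' outside the refractory period.
#'
#' @param time,D Diameter history (s, um); at least 1 s long.
#' @param params An [astro_params()].
#' @return A tibble `time`, `event` (one row per fired event).
#' @export
astro_trigger <- function(time, D, params = astro_params()) {
  if (diff(range(time)) < 1) abort("Diameter history must span at least 1 s.")
  dt <- stats::median(diff(time))
  rate <- c(0, diff(D)) / (dt * D)
  a <- dt / max(params$rate_smooth, dt)
  ema <- 0
  last <- -Inf
  out <- numeric(0)
  for (i in seq_along(rate)) {
    ema <- ema + a * (rate[i] - ema)
    if (ema < -params$constriction_rate_threshold &&
        (time[i] - last) >= params$refractory) {
      last <- time[i]
      out <- c(out, time[i])
    }
  }
  tibble(time = out, event = rep("astro_pulse", length(out)))
}

#' Sensitivity scan of the astrocytic trigger
#'
#' Counts events fired on a diameter history over a grid of thresholds and
#' refractory periods, for exploring the free parameters of the rule.
#'
#' @param time,D Diameter history.
#' @param thresholds Constriction-rate thresholds (per s).
#' @param refractories Refractory periods (s).
#' @return A tibble `threshold`, `refractory`, `n_events`.
#' @export
astro_sensitivity_scan <- function(time, D,
                                   thresholds = c(0.01, 0.02, 0.05),
                                   refractories = c(5, 10, 20)) {
  grid <- expand.grid(threshold = thresholds, refractory = refractories)
  n <- purrr::map2_int(grid$threshold, grid$refractory, function(th, rf) {
    nrow(astro_trigger(time, D, astro_params(constriction_rate_threshold = th,
                                             refractory = rf,
                                             pulse_duration = min(2, rf))))
  })
  tibble(threshold = grid$threshold, refractory = grid$refractory,
         n_events = n)
}
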