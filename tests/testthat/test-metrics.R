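test_that("amplitude and frequency metrics recover known waveforms", {
  t <- seq(0, 120, by = 0.2)
  x <- 10 + sin(2 * pi * 0.1 * t)
  m <- amplitude_and_frequency(t, x)
  expect_equal(m$amplitude_pct, 20, tolerance = 0.01)   # (11 - 9)/10 x 100
  expect_lt(abs(m$dominant_freq - 0.1), 0.01)
  expect_true(is.na(m$damping_time))                    # sustained
  # exponentially damped sine has a finite damping time
  xd <- 10 + exp(-t / 10) * sin(2 * pi * 0.1 * t)
  md <- amplitude_and_frequency(t, xd)
  expect_false(is.na(md$damping_time))
  expect_gt(md$damping_time, 5)
  expect_error(amplitude_and_frequency(t[1:3], x[1:3]), "short")
})

test_that("metrics are invariant to time shifts and diameter rescaling", {
  t <- seq(0, 100, by = 0.2)
  x <- 12 + 2 * sin(2 * pi * 0.12 * t)
  m1 <- amplitude_and_frequency(t, x)
  m2 <- amplitude_and_frequency(t + 55, x)
  m3 <- amplitude_and_frequency(t, 3.7 * x)
  expect_equal(m1$amplitude_pct, m2$amplitude_pct)
  expect_equal(m1$amplitude_pct, m3$amplitude_pct, tolerance = 1e-12)
  expect_equal(m1$dominant_freq, m2$dominant_freq)
})

test_that("component decomposition splits the oscillation amplitude", {
  t <- seq(0.2, 300, by = 0.2)
  base <- sin(2 * pi * 0.1 * t)
  mk <- function(amp_mr, amp_pd) {
    tibble::tibble(time = t, segment_id = "s",
                   D = 17.5 + (amp_mr + amp_pd) / 2 * base,
                   D_MR = -3 + amp_mr / 2 * base,
                   D_PD = 20 + amp_pd / 2 * base)
  }
  eq <- decompose_mr_pd(mk(1, 1), "s")
  expect_equal(eq$MR_share, 50, tolerance = 1e-6)
  expect_equal(eq$PD_share, 50, tolerance = 1e-6)
  # in-phase components with amplitudes 3.85 um and 0.65 um -> 85% / 15%
  pp <- decompose_mr_pd(mk(3.85, 0.65), "s")
  expect_equal(pp$MR_share, 85.6, tolerance = 0.2)
  expect_equal(pp$PD_share, 14.4, tolerance = 0.2)
  expect_equal(pp$MR_share + pp$PD_share, 100, tolerance = 0.5)
  flat <- tibble::tibble(time = t, segment_id = "s", D = 17.5,
                         D_MR = -3, D_PD = 20.5)
  expect_error(decompose_mr_pd(flat, "s"), "not oscillatory")
})

test_that("sigmoid onsets recover a known propagation speed", {
  t <- seq(0, 20, by = 0.05)
  mk <- function(t0) 15 + 2 / (1 + exp(-(t - t0) / 0.5))
  tr <- dplyr::bind_rows(
    tibble::tibble(time = t, cortical_depth = 600, D = mk(5)),
    tibble::tibble(time = t, cortical_depth = 200, D = mk(6)))
  on <- onset_and_propagation(tr)
  expect_equal(on$speed_onset, 400, tolerance = 0.05 * 400)
  expect_false(on$speed_is_upper_bound)
  # identical traces: infinite speed, flagged as an upper bound
  tr2 <- dplyr::bind_rows(
    tibble::tibble(time = t, cortical_depth = 600, D = mk(5)),
    tibble::tibble(time = t, cortical_depth = 200, D = mk(5)))
  on2 <- onset_and_propagation(tr2)
  expect_true(is.infinite(on2$speed_onset))
  expect_true(on2$speed_is_upper_bound)
})

test_that("noisy sigmoids still localise the onset within 0.2 s", {
  t <- seq(0, 20, by = 0.05)
  clean <- 15 + 2 / (1 + exp(-(t - 8) / 0.5))
  set.seed(42)
  deltas <- vapply(1:8, function(i) {
    noisy <- clean + rnorm(length(t), sd = 0.02 * 2)
    tr <- dplyr::bind_rows(
      tibble::tibble(time = t, cortical_depth = 600, D = clean),
      tibble::tibble(time = t, cortical_depth = 100, D = noisy))
    on <- onset_and_propagation(tr)
    abs(on$onsets$onset[on$onsets$cortical_depth == 100] -
        on$onsets$onset[on$onsets$cortical_depth == 600])
  }, numeric(1))
  expect_lt(stats::median(deltas), 0.2)
})

test_that("tidiers expose traces and summaries as tibbles", {
  t <- seq(0, 60, by = 0.2)
  m <- amplitude_and_frequency(t, 10 + sin(2 * pi * 0.1 * t))
  expect_s3_class(tidy(m), "tbl_df")
  expect_named(tidy(m), c("amplitude_pct", "dominant_freq", "damping_time",
                          "mean", "n_peaks"))
})
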