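test_that("stress transfer functions are quasi-linear sigmoids with the right tails", {
  p <- cellular_params()
  m <- ws_to_second_messengers(c(0, 300, 600), 600, p)
  expect_lt(m$IP3[1], 0.05)
  expect_equal(m$IP3[2], 0.5)
  expect_gt(m$IP3[3], 0.95)
  expect_identical(m$IP3, m$DAG)
  expect_true(all(diff(ws_to_second_messengers(seq(0, 600, 10), 600, p)$IP3) > 0))
  k <- ws_to_kir_op_smc(c(0, 300, 600), 600, p)
  expect_gt(k[1], 0.95)          # high open probability at low stress
  expect_lt(k[3], 0.05)
  e <- wss_to_kir_op_ec(c(0, 40), 40, p)
  expect_lt(e[1], 0.05)          # EC Kir deactivated without flow
})

test_that("the mechanotransduction lag is first order with unit gain", {
  x <- 0
  for (i in 1:100) x <- mechano_lag(x, 1, tau = 5, dt = 0.05)  # t = 5 s = tau
  expect_equal(x, 1 - exp(-1), tolerance = 1e-12)
  expect_equal(mechano_lag(0.4, 0.4, 5, 0.01), 0.4)
  expect_equal(mechano_lag(0, 1, 1e-9, 0.01), 1, tolerance = 1e-6)
})

test_that("crossbridge kinetics conserve fractions and match the null-space oracle", {
  p <- cellular_params()
  myo <- c(M = 1, Mp = 0, AMp = 0, AM = 0)
  for (i in 1:6000) {
    st <- crossbridge_step(myo, ca = 250, no = 0, dt = 5e-3, params = p, kh = 160)
    myo <- st$myo
    if (i %in% c(1, 10, 100)) expect_equal(sum(myo), 1, tolerance = 1e-9)
  }
  expect_equal(sum(myo), 1, tolerance = 1e-9)
  # independent oracle: stationary distribution from the rate matrix null space
  r <- xb_rates(250, 0, p, 160)
  A <- matrix(c(-r$k1, r$k_mlcp, 0, p$k7,
                r$k1, -(r$k_mlcp + p$k3), p$k4, 0,
                0, p$k3, -(p$k4 + r$k_mlcp), r$k1,
                0, 0, r$k_mlcp, -(r$k1 + p$k7)), 4, 4, byrow = TRUE)
  ns <- svd(A)$v[, 4]
  ns <- ns / sum(ns)
  expect_equal(unname(myo), ns, tolerance = 1e-4)
  expect_equal(unname(xb_steady_state(250, 0, p, 160)), ns, tolerance = 1e-9)
})

test_that("NO desensitises tone to calcium through MLCP", {
  p <- cellular_params()
  tones <- vapply(c(0, 2, 5, 10), function(no) {
    ss <- xb_steady_state(200, no, p, 160)
    (ss[["AMp"]] + p$w_am * ss[["AM"]])
  }, numeric(1))
  expect_true(all(diff(tones) < 0))
  # Ca-tone coupling weakens as NO rises: d tone / d Ca shrinks
  slope <- function(no) {
    t1 <- xb_steady_state(180, no, p, 160); t2 <- xb_steady_state(220, no, p, 160)
    (t2[["AMp"]] + p$w_am * t2[["AM"]]) - (t1[["AMp"]] + p$w_am * t1[["AM"]])
  }
  expect_gt(slope(0), slope(8))
})

test_that("wall mechanics balance passive distension and active constriction", {
  p <- cellular_params()
  expect_equal(segment_diameter(0, 500, 0.94, 16.4, p),
               passive_diameter(500, 16.4, p))
  d <- vapply(seq(0, 1, 0.1), segment_diameter, numeric(1),
              WS = 500, contractility = 0.94, d_active_max = 16.4, params = p)
  expect_true(all(diff(d) < 0))
  # myogenic tone worked example
  expect_equal(myogenic_tone_pct(21.5, 12.6), 41.4, tolerance = 0.05)
  # saturated passive diameter ~130% of the maximal active diameter
  expect_equal(passive_diameter(5000, 16.4, p) / 16.4, 1.3, tolerance = 1e-6)
})

test_that("per-segment calibration anchors the baseline state", {
  cal <- reference_calibration()
  p <- cellular_params()
  expect_equal(cal$x0, cal$WS0 / cal$WS_max)
  expect_true(cal$tone0 > 0 && cal$tone0 < 1)
  # the calibrated Hill midpoint reproduces the baseline tone
  ss <- xb_steady_state(p$ca_base, 0, p, cal$kh)
  tn <- (ss[["AMp"]] + p$w_am * ss[["AM"]])
  ss1 <- xb_steady_state(1e6, 0, p, 160)
  expect_equal(tn / (ss1[["AMp"]] + p$w_am * ss1[["AM"]]), cal$tone0,
               tolerance = 1e-6)
  # baseline diameter is recovered: passive minus calibrated tone
  d <- segment_diameter(cal$tone0, cal$WS0, cal$contractility,
                        cal$d_active_max, p)
  expect_equal(d, cal$d_active_max, tolerance = 1e-6)
})
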