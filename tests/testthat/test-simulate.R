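test_that("macro simulation runs are deterministic and carry coherent channels", {
  net <- tiny_network()
  s1 <- simulate_vasomotion(net, duration = 60, record = "arteriolar",
                            steady_window = 30)
  s2 <- simulate_vasomotion(net, duration = 60, record = "arteriolar",
                            steady_window = 30)
  expect_identical(s1$trace, s2$trace)
  expect_false(any(is.na(s1$trace$D)))
  expect_true(all(s1$trace$D > 0))
  # the commit is the candidate D_PD + D_MR unless a rate limit clipped it
  tr <- s1$trace[s1$trace$segment_id == "PA01_02", ]
  cand <- (tr$D_PD + tr$D_MR)[-1]
  d_prev <- tr$D[-nrow(tr)]
  d_new <- tr$D[-1]
  up <- 0.15 * 0.2 * d_prev
  dn <- 0.075 * 0.2 * d_prev
  dD <- d_new - d_prev
  expect_true(all(dD <= up + 1e-9 & dD >= -dn - 1e-9))
  inside <- dD < up - 1e-9 & dD > -dn + 1e-9
  expect_true(all(abs(d_new[inside] - cand[inside]) < 1e-9))
})

test_that("removing the myogenic delay abolishes sustained oscillation", {
  net <- tiny_network()
  s <- simulate_vasomotion(net, params = macro_params(MR_D = 0,
                                                      DR_dilation = 5,
                                                      DR_constriction = 5),
                           duration = 120, record = "PA01_02",
                           steady_window = 30)
  tr <- s$trace
  late <- tr$D[tr$time > 90]
  expect_lt((max(late) - min(late)) / mean(late), 5e-3)
})

test_that("a cellular segment started at its calibrated baseline stays put", {
  net <- default_network()
  sim <- simulate_cellular_pa(net, segments = "PA01_09", duration = 10,
                              init = "baseline",
                              stress_max = default_stress_max())
  d <- sim$trace$D[sim$trace$time > 2]
  expect_lt(diff(range(d)) / mean(d), 0.01)
})

test_that("virtual myography reproduces passive/active tone development", {
  cal <- reference_calibration()
  ipx <- seq(-15, 70, by = 5)   # ex-vivo pressures; in-silico = +25 mmHg
  pas <- run_pressure_myography(ipx, "passive", cal = cal)
  act <- run_pressure_myography(ipx, "active", cal = cal)
  expect_equal(myogenic_tone_pct(pas$D, pas$D), rep(0, length(ipx)))
  expect_true(all(diff(pas$D) > 0))                  # pure distension
  mt <- myogenic_tone_pct(pas$D, act$D)
  # tone develops with pressure and reaches tens of percent
  expect_gt(max(mt), 30)
  # maximal active diameter at an interior pressure near the lower
  # autoregulation limit (paper range 30-35 mmHg in-silico; ours ~40)
  pk_ip <- act$IP_insilico[which.max(act$D)]
  expect_gt(pk_ip, 28); expect_lt(pk_ip, 45)
  # 50% Kir inhibition constricts the vessel across physiological pressures
  actk <- run_pressure_myography(ipx, "active", inhibit = c(kir = 0.5),
                                 cal = cal)
  phys <- act$IP_insilico >= 40 & act$IP_insilico <= 75
  expect_true(all(actk$D[phys] < act$D[phys]))
  expect_error(run_pressure_myography(c(10, 5), "active", cal = cal),
               "increasing")
})

test_that("voltage clamp shows inward rectification and pressure-dependent RMR", {
  cal <- reference_calibration()
  iv20 <- run_voltage_clamp(ip = 20, cal = cal)
  sl <- diff(iv20$iv$I) / diff(iv20$iv$V)
  expect_true(any(sl < 0))                          # negative-slope region
  iv30 <- run_voltage_clamp(ip = 30, cal = cal)
  iv75 <- run_voltage_clamp(ip = 75, cal = cal)
  expect_gt(iv30$rmr, iv75$rmr)                     # max RMR near lower limit
  expect_gt(iv75$rmp, iv30$rmp)                     # RMP rises with pressure
  # I(RMP) = 0 by construction of the root
  I_at <- approx(iv30$iv$V, iv30$iv$I, xout = iv30$rmp)$y
  expect_lt(abs(I_at), 0.05 * max(abs(iv30$iv$I)))
  expect_error(run_voltage_clamp(v_grid = seq(-100, -95, 1), ip = 30,
                                 cal = cal), "zero crossing")
})

test_that("potassium challenges dilate at moderate and constrict at high doses", {
  cal <- reference_calibration()
  resp <- function(kex, params = cellular_params()) {
    sch <- tibble::tibble(t = c(0, 5), K_ex_smc = c(0, kex - 4))
    r <- run_mediator_challenge(sch, ip = 50, duration = 35, cal = cal,
                                params = params)
    d0 <- mean(r$D[r$time < 5])
    list(peak = (max(r$D[r$time >= 5 & r$time < 20]) / d0 - 1) * 100,
         v_end = tail(r$V_smc, 1),
         d_end = (tail(r$D, 1) / d0 - 1) * 100)
  }
  r8 <- resp(8); r60 <- resp(60)
  expect_gt(r8$peak, 3)                       # dilation at 8 mM
  expect_lt(r60$d_end, -5)                    # sustained constriction at 60 mM
  expect_gt(r60$v_end, -27); expect_lt(r60$v_end, -15)  # ~ -20 mV
})

test_that("the washout hyperpolarisation overshoot is Kir dependent", {
  cal <- reference_calibration()
  sch <- tibble::tibble(t = c(0, 5, 25), K_ex_smc = c(0, 56, 0))
  r1 <- run_mediator_challenge(sch, ip = 50, duration = 40, cal = cal)
  p0 <- cellular_params(g_kir_smc = 1e-6)
  cal0 <- calibrate_cellular(default_network(), "PA01_09", p0,
                             stress_max = default_stress_max())
  r0 <- run_mediator_challenge(sch, ip = 50, duration = 40, params = p0,
                               cal = cal0)
  over <- function(r) mean(r$V_smc[r$time < 5]) -
    min(r$V_smc[r$time > 25 & r$time < 35])
  expect_gt(over(r1), 30)
  expect_lt(over(r0), 20)
  expect_gt(over(r1) / over(r0), 2)
})

test_that("NO challenges give dose-dependent dilation maximal at the top dose", {
  cal <- reference_calibration()
  peaks <- vapply(c(2.5, 5, 10), function(no) {
    sch <- tibble::tibble(t = c(0, 5), NO = c(0, no))
    r <- run_mediator_challenge(sch, ip = 50, duration = 25, cal = cal)
    d0 <- mean(r$D[r$time < 5])
    (max(r$D[r$time >= 5]) / d0 - 1) * 100
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
  expect_gt(peaks[3], 10)
})

test_that("configs dispatch to runners and results serialise", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("mode: myography", "ip_steps: [5, 15, 25]"), cfg_path)
  cfg <- read_sim_config(cfg_path)
  res <- run_simulation(cfg)
  expect_s3_class(res, "tbl_df")
  expect_named(res, c("IP_exvivo", "D_passive", "D_active", "MT_pct"))
  out <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(res, out)
  back <- utils::read.csv(out)
  expect_equal(nrow(back), 3)
  j <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(list(amplitude_pct = 25.3, dominant_freq = 0.1), j)
  parsed <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(parsed$amplitude_pct, 25.3)
  nocfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines("duration: 5", nocfg)
  expect_error(read_sim_config(nocfg), "mode")
})
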