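# fast repeated pressure solves on a fixed topology (constant viscosity)
.make_fast_hemo <- function(net, abnp, vbnp, visc = viscosity_model()) {
  sg <- net$segments
  ix <- .hemo_index(net)
  mu <- apparent_viscosity(visc, sg$diameter)
  gcoef <- pi * .QCONV / (128 * mu * sg$length)
  pb <- numeric(ix$n); pb[ix$abn] <- abnp; pb[ix$vbn] <- vbnp
  bnd <- c(ix$abn, ix$vbn)
  function(D_all) {
    g <- gcoef * D_all^4
    A <- sparseMatrix(i = c(ix$ia, ix$ib, ix$ia, ix$ib),
                      j = c(ix$ib, ix$ia, ix$ia, ix$ib),
                      x = c(-g, -g, g, g), dims = c(ix$n, ix$n))
    p <- pb
    p[ix$int] <- as.numeric(solve(A[ix$int, ix$int],
                                  -(A[ix$int, bnd] %*% pb[bnd])))
    Q <- g * (p[ix$ia] - p[ix$ib])
    list(IP = (p[ix$ia] + p[ix$ib]) / 2, Q = Q, mu = mu)
  }
}

# vectorised mediator levels for a set of depths (plain list, hot path)
.mediator_levels <- function(t, protocol, depths) {
  n <- length(depths)
  if (is.null(protocol)) {
    return(list(NO = numeric(n), glu = numeric(n),
                kex_smc = numeric(n), kex_ec = numeric(n)))
  }
  rise <- protocol$t_on + no_onset_delay(depths, protocol)
  lv <- protocol$levels
  if (protocol$kind == "impulse") {
    no <- ifelse(t < rise, 0, lv[["NO"]] * exp(-(t - rise) / protocol$decay_tau))
    box <- as.numeric(t >= rise & t < rise + 0.5)
  } else {
    off <- protocol$t_off + (rise - protocol$t_on)
    no <- ifelse(t < rise, 0,
                 ifelse(t <= off, lv[["NO"]],
                        lv[["NO"]] * exp(-(t - off) / protocol$decay_tau)))
    box <- as.numeric(t >= rise & t <= off)
  }
  list(NO = no, glu = lv[["glutamate"]] * box,
       kex_smc = lv[["K_ex_smc"]] * box, kex_ec = lv[["K_ex_ec"]] * box)
}

#' Simulate a cellular-model penetrating arteriole in the network
#'
#' Replaces the segments of one PA (or any subset of PA segments) by the
#' cellular SMC/EC model and advances the coupled hemodynamic-vasodynamic
#' loop: pressures are re-solved every `dt1` seconds with all other network
#' segments held at their autoregulated diameters, and the cellular states
#' integrate at the fine step `params$dt` within each window. Optional
#' neurogenic stimuli ([stimulus_protocol()]) release NO, glutamate and
#' potassium with depth-dependent NO onset.
#'
#' @param net A `vd_network`.
#' @param pa Index of the PA to make cellular (ignored when `segments`
#'   given).
#' @param segments Optional explicit character vector of PA segment ids.
#' @param params A [cellular_params()].
#' @param duration Simulated time (s).
#' @param protocol Optional [stimulus_protocol()].
#' @param gap_junctions Couple adjacent segments electrically (homocellular
#'   gap junctions in both layers); `FALSE` removes them.
#' @param init `"baseline"` starts at the calibrated autoregulated fixed
#'   point (flat until stimulated); `"onset"` perturbs the messenger pools
#'   by `perturb`, mimicking simulation-onset imbalance, and elicits the
#'   damped vasomotion transient.
#' @param perturb Messenger perturbation for `init = "onset"`.
#' @param abnp,vbnp Boundary pressures (mmHg).
#' @param dt1 Hemodynamic update interval (s).
#' @param record_dt Recording interval (s).
#' @param cal Optional precomputed [calibrate_cellular()] result.
#' @param stress_max Optional precomputed [record_max_stresses()] result.
#' @return A `vd_cell_sim`: list with `trace` (long tibble `time`,
#'   `segment_id`, `cortical_depth`, `D`, `V_smc`, `V_ec`, `Ca`, `tone`,
#'   `WS`, `NO`), `cal`, `params`, metadata.
#' @export
simulate_cellular_pa <- function(net, pa = 1, segments = NULL,
                                 params = cellular_params(), duration = 60,
                                 protocol = NULL, gap_junctions = TRUE,
                                 init = c("baseline", "onset"),
                                 perturb = 0.08, abnp = 60, vbnp = 10,
                                 dt1 = 0.2, record_dt = 0.05,
                                 cal = NULL, stress_max = NULL) {
  init <- match.arg(init)
  sg <- net$segments
  segments <- segments %||% sg$id[grepl(sprintf("^PA%02d_", pa), sg$id)]
  if (!length(segments)) abort("No PA segments selected.")
  cal <- cal %||% calibrate_cellular(net, segments, params, abnp, vbnp,
                                     stress_max = stress_max)
  six <- match(segments, sg$id)
  n <- length(six)

  adj <- NULL
  if (gap_junctions && n > 1) {
    cp <- arteriolar_coupling(net)
    keep <- match(segments, cp$ids)
    adj <- cp$adjacency[keep, keep, drop = FALSE]
  }

  fast <- .make_fast_hemo(net, abnp, vbnp)
  D_all <- ifelse(sg$is_arteriolar, sg$d_active_max, sg$diameter)

  st <- .cell_state_init(cal, params)
  if (init == "onset") {
    st$m <- st$m + perturb
    st$kop <- st$kop - perturb
  }

  n_win <- round(duration / dt1)
  n_sub <- round(dt1 / params$dt)
  rec_every <- max(1L, round(record_dt / dt1))
  n_rec <- n_win %/% rec_every
  recD <- matrix(NA_real_, n_rec, n); recV <- recD; recE <- recD
  recC <- recD; recT <- recD; recW <- recD; recN <- recD
  rec_t <- numeric(n_rec)
  depths <- cal$cortical_depth
  ri <- 0L
  for (i in seq_len(n_win)) {
    tnow <- (i - 1L) * dt1
    D_all[six] <- st$D
    hs <- fast(D_all)
    ip <- hs$IP[six]
    wss <- 32 * hs$mu[six] * abs(hs$Q[six]) / (pi * D_all[six]^3) * .WSSCONV
    med <- .mediator_levels(tnow, protocol, depths)
    st <- .cell_advance(st, cal, params, ip, wss, med, n_sub, adj)
    if (i %% rec_every == 0L) {
      ri <- ri + 1L
      rec_t[ri] <- tnow + dt1
      recD[ri, ] <- st$D; recV[ri, ] <- st$v; recE[ri, ] <- st$vec
      recC[ri, ] <- st$ca; recT[ri, ] <- st$tone
      recW[ri, ] <- ip * st$D / cal$wall_thickness
      recN[ri, ] <- med$NO
    }
  }
  trace <- tibble(time = rep(rec_t, n),
                  segment_id = rep(segments, each = n_rec),
                  cortical_depth = rep(depths, each = n_rec),
                  D = as.vector(recD), V_smc = as.vector(recV),
                  V_ec = as.vector(recE), Ca = as.vector(recC),
                  tone = as.vector(recT), WS = as.vector(recW),
                  NO = as.vector(recN))
  structure(list(trace = trace, cal = cal, params = params,
                 mode = "cellular_pa", abnp = abnp, vbnp = vbnp,
                 duration = duration, gap_junctions = gap_junctions,
                 record_ids = segments),
            class = c("vd_cell_sim", "vd_sim"))
}

# cached reference calibration (250 um segment of PA 1, default network)
.vd_cache <- new.env(parent = emptyenv())
.reference_cal <- function(params = cellular_params()) {
  if (is.null(.vd_cache$ref_cal)) {
    net <- build_network(network_config())
    mx <- record_max_stresses(net)
    .vd_cache$ref_net <- net
    .vd_cache$ref_mx <- mx
    .vd_cache$ref_cal <- calibrate_cellular(net, "PA01_09", params,
                                            stress_max = mx)
  }
  .vd_cache$ref_cal
}

#' Virtual pressure myography
#'
#' Steps the intravascular pressure of an isolated, endothelium-denuded
#' cellular segment (no flow: zero wall shear stress, EC Kir deactivated,
#' myoendothelial junction removed) and records the steady-state diameter.
#' `mode = "passive"` clamps tone to zero (calcium-free bath); `"active"`
#' lets the myogenic machinery respond. Ex-vivo pressures map to in-silico
#' ones through the constant tissue-load offset
#' (`IP_insilico = IP_exvivo + 25` mmHg).
#'
#' @param ip_steps Increasing ex-vivo pressures (mmHg).
#' @param mode `"active"` or `"passive"`.
#' @param params A [cellular_params()].
#' @param inhibit Named multipliers on channel conductances, e.g.
#'   `c(kir = 0.5)` for 50% Kir inhibition; names among
#'   `dep`, `kir`, `kv`, `bk`.
#' @param cal One-row calibration (defaults to the 250-um reference
#'   segment of the default network).
#' @return A tibble `IP_exvivo`, `IP_insilico`, `D`, `V_smc`, `Ca`, `tone`,
#'   plus `MT_pct` when both modes are combined via [myography_mt()].
#' @export
run_pressure_myography <- function(ip_steps, mode = c("active", "passive"),
                                   params = cellular_params(),
                                   inhibit = NULL, cal = NULL) {
  mode <- match.arg(mode)
  if (is.unsorted(ip_steps, strictly = TRUE)) {
    abort("`ip_steps` must be strictly increasing (stepwise inflation).")
  }
  cal <- cal %||% .reference_cal(params)
  cal1 <- cal[1, ]
  p <- params
  p$g_mgj <- 0  # denuded: no myoendothelial junction
  inh <- c(dep = 1, kir = 1, kv = 1, bk = 1)
  if (!is.null(inhibit)) inh[names(inhibit)] <- inhibit
  rows <- purrr::map(ip_steps, function(ipx) {
    ipi <- ipx + params$ip_exvivo_offset
    ss <- .cell_steady(cal1, p, ip = ipi, wss = 0,
                       tone_clamp = if (mode == "passive") 0 else NULL,
                       inhibit = inh)
    tibble(IP_exvivo = ipx, IP_insilico = ipi, D = ss$D, V_smc = ss$v,
           Ca = ss$ca, tone = ss$tone)
  })
  dplyr::bind_rows(rows)
}

#' Myogenic tone curve from paired myography runs
#'
#' Runs [run_pressure_myography()] in passive and active mode over the same
#' pressure steps and returns `MT = (D_passive - D_active)/D_passive x 100`.
#'
#' @inheritParams run_pressure_myography
#' @return A tibble `IP_exvivo`, `D_passive`, `D_active`, `MT_pct`.
#' @export
myography_mt <- function(ip_steps, params = cellular_params(),
                         inhibit = NULL, cal = NULL) {
  pas <- run_pressure_myography(ip_steps, "passive", params, inhibit, cal)
  act <- run_pressure_myography(ip_steps, "active", params, inhibit, cal)
  tibble(IP_exvivo = ip_steps, D_passive = pas$D, D_active = act$D,
         MT_pct = myogenic_tone_pct(pas$D, act$D))
}

#' Virtual voltage clamp of the smooth-muscle cell
#'
#' Clamps the SMC membrane potential across a grid, lets the segment's
#' slow states settle (diameter, wall stress, messengers and calcium all at
#' their steady state for the clamped potential) and reports the total
#' steady-state membrane current. The resting membrane potential (RMP) is
#' the zero crossing of the I-V curve and the resting membrane resistance
#' (RMR) the reciprocal slope there.
#'
#' @param v_grid Clamp potentials (mV); should span -100 to 40.
#' @param ip In-silico intravascular pressure (mmHg).
#' @param params A [cellular_params()].
#' @param cal One-row calibration (default: reference segment).
#' @return A list of class `vd_iv`: `iv` (tibble `V`, `I`), `rmp` (mV),
#'   `rmr` (arbitrary resistance units).
#' @export
run_voltage_clamp <- function(v_grid = seq(-100, 40, by = 2), ip = 30,
                              params = cellular_params(), cal = NULL) {
  cal <- cal %||% .reference_cal(params)
  cal1 <- cal[1, ]
  p <- params
  p$g_mgj <- 0
  ek <- nernst_k(p$kex_smc0, p$k_in)
  tn <- .tone_norm(p)
  ct <- .c_tone(p)
  current_at <- function(v) {
    # settle diameter/tone at the clamped potential
    ca <- p$ca_min + p$ca_range * sigmoid01(v, p$vca_k, cal1$vca_mid)
    ss <- xb_steady_state(ca, 0, p, cal1$kh)
    tone <- (ss[[3]] + p$w_am * ss[[4]]) / tn
    D <- cal1$d_active_max
    for (i in 1:200) {
      ws <- max(ip * D / cal1$wall_thickness, 0)
      Dn <- passive_diameter(ws, cal1$d_active_max, p) -
        ct * cal1$contractility * tone * cal1$d_active_max
      if (Dn <= 0) Dn <- 0.05 * cal1$d_active_max
      if (abs(Dn - D) < 1e-10) break
      D <- D + 0.3 * (Dn - D)
    }
    ws <- max(ip * D / cal1$wall_thickness, 0)
    m <- sigmoid01(ws / cal1$WS_max, p$sig_k, cal1$x0)
    kop <- 1 - m
    gd <- cal1$gd0 * (2 * m)^p$mech_gain
    gkir <- p$g_kir_smc * kop * .kir_rect(v, ek, p$kir_rect_min)
    gkv <- p$g_kv * sigmoid01(v, 0.14, -25)
    gbk <- p$g_bk * sigmoid01(v, 0.1, -20)
    gd * (v - p$e_dep) + (gkir + gkv + gbk) * (v - ek)
  }
  I <- vapply(v_grid, current_at, numeric(1))
  cross <- which(I[-1] * I[-length(I)] <= 0 & is.finite(I[-1]))
  if (!length(cross)) abort("No zero crossing of I(V) on the clamp grid; widen `v_grid`.")
  k <- cross[1]
  rmp <- uniroot(current_at, c(v_grid[k], v_grid[k + 1]), tol = 1e-8)$root
  dv <- 0.5
  slope <- (current_at(rmp + dv) - current_at(rmp - dv)) / (2 * dv)
  structure(list(iv = tibble(V = v_grid, I = I), rmp = rmp, rmr = 1 / slope,
                 ip = ip),
            class = "vd_iv")
}

#' @export
print.vd_iv <- function(x, ...) {
  cat("<vd_iv> IP =", x$ip, "mmHg; RMP =", round(x$rmp, 1),
      "mV; RMR =", signif(x$rmr, 3), "\n")
  invisible(x)
}

#' Delay-chain calibration of the cellular oscillator
#'
#' Runs the single reference segment in the network from the
#' simulation-onset perturbation, detects oscillation cycles and measures
#' the component lags of the delayed myogenic loop: wall-stress trough to
#' membrane-potential trough, potential trough to calcium trough, calcium
#' trough to diameter peak (the dilation phase), and the corresponding
#' cumulative constriction-phase lag (wall-stress peak to diameter trough).
#' The oscillation period is the mean diameter peak-to-peak interval.
#'
#' @param net A `vd_network` (default network if `NULL`).
#' @param params A [cellular_params()].
#' @param duration Run length (s).
#' @param segment_id Cellular segment (default: the 250-um reference).
#' @return A list of class `vd_delay_chain`: `lags` (named dilation-phase
#'   lags, s), `dilation_total`, `constriction_total`, `period` (s),
#'   `frequency` (Hz), and the run `trace`.
#' @export
calibrate_delay_chain <- function(net = NULL, params = cellular_params(),
                                  duration = 90, segment_id = "PA01_09") {
  if (is.null(net)) {
    .reference_cal(params)  # populate cache
    net <- .vd_cache$ref_net
    mx <- .vd_cache$ref_mx
  } else {
    mx <- record_max_stresses(net)
  }
  sim <- simulate_cellular_pa(net, segments = segment_id, params = params,
                              duration = duration, init = "onset",
                              stress_max = mx)
  tr <- sim$trace
  t <- tr$time
  win <- t > 5 & t < duration - 5
  pk_of <- function(y, sign = 1) {
    y <- sign * y
    i <- which(diff(sign(diff(y))) < 0) + 1L
    i[win[i] & y[i] > stats::quantile(y[win], 0.6)]
  }
  d_pk <- pk_of(tr$D)
  if (length(d_pk) < 3) {
    abort("Trace is not oscillatory enough to calibrate the delay chain.")
  }
  period <- mean(diff(t[d_pk]))
  nearest_before <- function(cands, t_ref) {
    if (is.na(t_ref)) return(NA_real_)
    ok <- t[cands] <= t_ref & t[cands] > t_ref - period
    if (!any(ok)) return(NA_real_)
    max(t[cands][ok])
  }
  ws_tr <- pk_of(tr$WS, -1); v_tr <- pk_of(tr$V_smc, -1); ca_tr <- pk_of(tr$Ca, -1)
  ws_pk <- pk_of(tr$WS); v_pk <- pk_of(tr$V_smc); ca_pk <- pk_of(tr$Ca)
  d_tr <- pk_of(tr$D, -1)
  lag_rows <- purrr::map(t[d_pk], function(tp) {
    tc <- nearest_before(ca_tr, tp)
    tv <- nearest_before(v_tr, tc)
    tw <- nearest_before(ws_tr, tv)
    c(ws_v = tv - tw, v_ca = tc - tv, ca_d = tp - tc)
  })
  lags <- colMeans(do.call(rbind, lag_rows), na.rm = TRUE)
  con_rows <- purrr::map_dbl(t[d_tr], function(tp) {
    tw <- nearest_before(ws_pk, tp)
    tp - tw
  })
  structure(list(lags = lags, dilation_total = sum(lags),
                 constriction_total = mean(con_rows, na.rm = TRUE),
                 period = period, frequency = 1 / period,
                 trace = tr),
            class = "vd_delay_chain")
}

#' @export
print.vd_delay_chain <- function(x, ...) {
  cat("<vd_delay_chain> dilation lags:",
      paste(sprintf("%s=%.2fs", names(x$lags), x$lags), collapse = ", "),
      "| total", round(x$dilation_total, 2), "s; constriction",
      round(x$constriction_total, 2), "s; period", round(x$period, 2),
      "s (", round(x$frequency, 3), "Hz )\n")
  invisible(x)
}

#' Mediator challenge on an isolated cellular segment
#'
#' Integrates a single endothelium-denuded segment at fixed intravascular
#' pressure and no flow while stepping extracellular potassium, glutamate
#' and/or NO/cGMP according to a schedule, reproducing bath-application
#' protocols. Returns the full state trace.
#'
#' @param schedule Tibble with columns `t` plus any of `K_ex_smc`,
#'   `K_ex_ec`, `glutamate`, `NO` (levels held constant between listed
#'   times; potassium columns are increments above baseline, i.e. a 60 mM
#'   bath is `K_ex_smc = 56`).
#' @param ip In-silico intravascular pressure (mmHg).
#' @param duration Total time (s); defaults to the schedule's end.
#' @param params A [cellular_params()].
#' @param cal One-row calibration (default: reference segment).
#' @param denuded Remove the endothelium (myoendothelial junction).
#' @param record_dt Recording interval (s).
#' @param settle Unrecorded settling time (s) before the schedule starts.
#' @return A tibble `time`, `D`, `V_smc`, `Ca`, `tone`, `WS`, plus the
#'   applied mediator levels.
#' @export
run_mediator_challenge <- function(schedule, ip = 50, duration = NULL,
                                   params = cellular_params(), cal = NULL,
                                   denuded = TRUE, record_dt = 0.1,
                                   settle = 30) {
  cal <- cal %||% .reference_cal(params)
  cal1 <- cal[1, ]
  p <- params
  if (denuded) p$g_mgj <- 0
  duration <- duration %||% max(schedule$t)
  lvl <- function(col, tnow) {
    if (!col %in% names(schedule)) return(0)
    i <- findInterval(tnow, schedule$t)
    if (i < 1) 0 else schedule[[col]][i]
  }
  # settle dynamically to the resting state at this pressure
  st <- .cell_state_init(cal1, p)
  dt1 <- 0.2
  med0 <- list(NO = 0, glu = 0, kex_smc = 0, kex_ec = 0)
  for (i in seq_len(round(settle / dt1))) {
    st <- .cell_advance(st, cal1, p, ip = ip, wss = 0, med = med0,
                        n_sub = round(dt1 / p$dt), adj = NULL)
  }
  n_win <- round(duration / dt1)
  rec_every <- max(1L, round(record_dt / dt1))
  out <- vector("list", n_win %/% rec_every)
  ri <- 0L
  n_sub <- round(dt1 / p$dt)
  for (i in seq_len(n_win)) {
    tnow <- (i - 1L) * dt1
    med <- list(NO = lvl("NO", tnow), glu = lvl("glutamate", tnow),
                kex_smc = lvl("K_ex_smc", tnow), kex_ec = lvl("K_ex_ec", tnow))
    st <- .cell_advance(st, cal1, p, ip = ip, wss = 0, med = med,
                        n_sub = n_sub, adj = NULL)
    if (i %% rec_every == 0L) {
      ri <- ri + 1L
      out[[ri]] <- tibble(time = tnow + dt1, D = st$D, V_smc = st$v,
                          Ca = st$ca, tone = st$tone,
                          WS = ip * st$D / cal1$wall_thickness,
                          K_ex_smc = med$kex_smc, NO = med$NO,
                          glutamate = med$glu)
    }
  }
  dplyr::bind_rows(out)
}
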