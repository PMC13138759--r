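#' Parameters of the cellular PA segment model
#'
#' A reduced phenomenological model of an arteriolar smooth-muscle cell
#' (SMC) and endothelial cell (EC) pair wrapped around each PA segment.
#' Wall stress drives second messengers (IP3/DAG) and downregulates SMC
#' inward-rectifier (Kir) open probability through first-order
#' mechanotransduction lags (`tau_mct`); membrane potential relaxes toward
#' a conductance-weighted balance of a lumped depolarising current
#' (TRPM4/TMEM16A), Kir, Kv and BK currents, the myoendothelial gap
#' junction (MGJ) and homocellular gap junctions; cytosolic calcium follows
#' voltage-operated channel activation with asymmetric rise/fall time
#' constants; and a four-state crossbridge model converts calcium into
#' wall tone, with the NO/cGMP/PKG pathway accelerating myosin
#' dephosphorylation (tone desensitisation to calcium).
#'
#' All conductances are dimensionless weights (the membrane equation is
#' normalised by capacitance); `mech_gain` is the exponent shaping how
#' steeply the depolarising conductance follows the messenger pool around
#' its baseline, the one free parameter calibrated so a single in-network
#' segment exhibits weakly damped ~0.1 Hz vasomotion (see the methods
#' vignette).
#'
#' @param tau_mct Mechanotransduction time constant (s); 1-20 s
#'   physiological, lowered by NPY-receptor activation.
#' @param tau_vm,tau_ec Membrane time constants of SMC and EC (s).
#' @param tau_ca_rise,tau_ca_fall Calcium rise (constriction) and fall
#'   (dilation) time constants (s).
#' @param tau_glu Glu-BK microdomain calcium time constant (s).
#' @param sig_k,x0_frac Steepness of the quasi-linear sigmoidal transfer
#'   functions and default midpoint (fraction of the stress maximum).
#' @param g_kir_smc,g_kv,g_bk,g_kir_ec,g_mgj,g_mgj_ec,g_gap,g_gap_ec
#'   Conductance weights (SMC Kir, Kv, BK; EC Kir; MGJ seen from each side;
#'   homocellular gap junctions per side).
#' @param kir_rect_min Residual Kir conductance fraction under full
#'   rectification block.
#' @param tau_rect Time constant (s) of the rectification-block kinetics.
#' @param e_dep Reversal potential of the lumped depolarising current (mV).
#' @param k_in Intracellular potassium (mM) for the Nernst potential.
#' @param kex_smc0,kex_ec0 Baseline extracellular potassium (mM).
#' @param ca_min,ca_range VOCC calcium floor and span (nM).
#' @param vca_k Steepness of VOCC activation (per mV).
#' @param k1max,k2,k3,k4,k7 Crossbridge rate constants (per s): `k1max`
#'   maximal MLCK phosphorylation, `k2` MLCP dephosphorylation, `k3`/`k4`
#'   attach/detach, `k7` latch-bridge detachment.
#' @param beta_no MLCP potentiation per AU of NO/cGMP.
#' @param b_glu,b_no BK-channel potentiation per unit of Glu-BK microdomain
#'   calcium and NO.
#' @param glu_scale Microdomain calcium per AU of glutamate.
#' @param w_am Latch-bridge weight in the tone readout.
#' @param hill_n Hill coefficient of MLCK activation by calcium.
#' @param mech_gain Mechanosensitivity exponent (calibrated).
#' @param v_base,ca_base Baseline SMC potential (mV) and calcium (nM) the
#'   per-segment calibration anchors to.
#' @param mt_max Maximal myogenic tone (fraction of passive diameter) at
#'   full crossbridge activation for the reference segment.
#' @param passive_ratio Maximal passive / maximal active diameter.
#' @param K_pd Passive distension rate constant (per mmHg).
#' @param ip_exvivo_offset In-silico minus ex-vivo intravascular pressure
#'   (mmHg); ex-vivo preparations lack ~25 mmHg of tissue load.
#' @param dt Integration step (s) of the fixed-step cellular integrator.
#' @return A list of class `vd_cellular_params`.
#' @export
cellular_params <- function(tau_mct = 5, tau_vm = 0.3, tau_ec = 0.2,
                            tau_ca_rise = 0.6, tau_ca_fall = 1.6,
                            tau_glu = 0.5,
                            sig_k = 8, x0_frac = NULL,
                            g_kir_smc = 0.3, g_kv = 0.12, g_bk = 0.08,
                            g_kir_ec = 0.4, g_mgj = 0.03, g_mgj_ec = 1,
                            kir_rect_min = 0.15, tau_rect = 0.8,
                            g_gap = 1, g_gap_ec = 2,
                            e_dep = 0, k_in = 140,
                            kex_smc0 = 4, kex_ec0 = 3,
                            ca_min = 80, ca_range = 280, vca_k = 1,
                            k1max = 1.2, k2 = 0.55,
                            k3 = 2.43, k4 = 0.594, k7 = 0.1215,
                            beta_no = 0.6, b_glu = 1, b_no = 0.15,
                            glu_scale = 1, w_am = 0.3, hill_n = 2,
                            mech_gain = 2.5,
                            v_base = -40, ca_base = 140,
                            mt_max = 0.42, passive_ratio = 1.3,
                            K_pd = 3e-3, ip_exvivo_offset = 25,
                            dt = 1e-3) {
  stopifnot(tau_mct > 0, tau_vm > 0, tau_ec > 0, tau_ca_rise > 0,
            tau_ca_fall > 0, dt > 0,
            all(c(g_kir_smc, g_kv, g_bk, g_kir_ec, g_mgj, g_gap) >= 0))
  structure(as.list(environment()), class = "vd_cellular_params")
}

#' Quasi-linear sigmoidal transfer function
#'
#' `1 / (1 + exp(-k (x - x0)))`: near-linear on the central range, used for
#' all stress-to-signal transfer functions of the cellular model.
#'
#' @param x Input (typically a stress normalised by its maximum).
#' @param k Steepness.
#' @param x0 Midpoint.
#' @return Value in (0, 1).
#' @export
sigmoid01 <- function(x, k = 8, x0 = 0.5) 1 / (1 + exp(-k * (x - x0)))

#' Wall stress to second-messenger drive
#'
#' Steady-state IP3 and DAG targets as a quasi-linear sigmoid of the
#' normalised wall stress; the realised pools follow with the
#' mechanotransduction lag ([mechano_lag()]).
#'
#' @param WS Wall stress (mmHg), non-negative.
#' @param WS_max Stress normaliser from [record_max_stresses()].
#' @param params A [cellular_params()].
#' @param x0 Optional midpoint override (per-segment calibration).
#' @return A list with `IP3` and `DAG` targets in \[0, 1\].
#' @export
ws_to_second_messengers <- function(WS, WS_max, params = cellular_params(),
                                    x0 = NULL) {
  stopifnot(all(WS >= 0), WS_max > 0)
  s <- sigmoid01(WS / WS_max, params$sig_k, x0 %||% params$x0_frac %||% 0.5)
  list(IP3 = s, DAG = s)
}

#' Wall-stress and shear-stress control of Kir open probability
#'
#' SMC Kir open probability is the decreasing mirror sigmoid of normalised
#' wall stress (high at low stress); EC Kir open probability increases with
#' normalised wall shear stress and is deactivated without flow.
#'
#' @param WS,WSS Stresses (mmHg, dyn/cm2).
#' @param WS_max,WSS_max Normalisers.
#' @param params A [cellular_params()].
#' @param x0 Optional midpoint override.
#' @return Open probability in (0, 1).
#' @export
ws_to_kir_op_smc <- function(WS, WS_max, params = cellular_params(), x0 = NULL) {
  stopifnot(all(WS >= 0), WS_max > 0)
  1 - sigmoid01(WS / WS_max, params$sig_k, x0 %||% params$x0_frac %||% 0.5)
}

#' @rdname ws_to_kir_op_smc
#' @export
wss_to_kir_op_ec <- function(WSS, WSS_max, params = cellular_params(), x0 = NULL) {
  stopifnot(all(WSS >= 0), WSS_max > 0)
  sigmoid01(WSS / WSS_max, params$sig_k, x0 %||% 0.5)
}

#' First-order mechanotransduction lag
#'
#' One explicit-update step of `value -> target` relaxation with unit DC
#' gain: `value + (target - value) (1 - exp(-dt/tau))`.
#'
#' @param current Current value.
#' @param target Target value.
#' @param tau Time constant (s).
#' @param dt Step (s).
#' @return Updated value.
#' @export
mechano_lag <- function(current, target, tau, dt) {
  stopifnot(tau > 0)
  current + (target - current) * (1 - exp(-dt / tau))
}

#' Nernst potential of potassium
#'
#' @param kex Extracellular potassium (mM).
#' @param k_in Intracellular potassium (mM).
#' @return mV (RT/F = 26.7 mV at 37 C).
#' @export
nernst_k <- function(kex, k_in = 140) 26.7 * log(kex / k_in)

# Kir inward-rectification factor: polyamine block collapses the
# conductance as V rises above E_K (negative-slope region of the I-V
# curve), leaving a small residual outward conductance. The block has its
# own kinetics (`tau_rect`): after an abrupt negative shift of E_K the
# channel transiently stays unblocked, producing the washout
# hyperpolarisation overshoot.
.kir_rect <- function(v, ek, r0 = 0.15) {
  r0 + (1 - r0) / (1 + exp((v - (ek + 10)) / 7))
}

#' Crossbridge rate matrix and steady state
#'
#' Four-state crossbridge kinetics over (M, Mp, AMp, AM): phosphorylation
#' `M -> Mp` and `AM -> AMp` at the calcium-dependent MLCK rate;
#' dephosphorylation `Mp -> M` and `AMp -> AM` at the MLCP rate (raised by
#' NO/cGMP); attachment/detachment `Mp <-> AMp`; latch-bridge detachment
#' `AM -> M`.
#'
#' @param ca Cytosolic calcium (nM).
#' @param no NO/cGMP level (AU).
#' @param params A [cellular_params()].
#' @param kh Hill midpoint (nM) of MLCK activation (per-segment
#'   calibration; defaults to a mid-physiological 160 nM).
#' @return `xb_rates()`: list with `k1` (MLCK) and `k_mlcp`;
#'   `xb_steady_state()`: the stationary fractions (M, Mp, AMp, AM).
#' @export
xb_rates <- function(ca, no = 0, params = cellular_params(), kh = 160) {
  k1 <- params$k1max * ca^params$hill_n / (ca^params$hill_n + kh^params$hill_n)
  list(k1 = k1, k_mlcp = params$k2 * (1 + params$beta_no * no))
}

#' @rdname xb_rates
#' @export
xb_steady_state <- function(ca, no = 0, params = cellular_params(), kh = 160) {
  r <- xb_rates(ca, no, params, kh)
  k1 <- r$k1; k2 <- r$k_mlcp
  A <- matrix(c(-k1, k2, 0, params$k7,
                k1, -(k2 + params$k3), params$k4, 0,
                0, params$k3, -(params$k4 + k2), k1,
                0, 0, k2, -(k1 + params$k7)),
              4, 4, byrow = TRUE)
  A[4, ] <- 1
  st <- base::solve(A, c(0, 0, 0, 1))
  setNames(st, c("M", "Mp", "AMp", "AM"))
}

#' One crossbridge integration step
#'
#' Explicit update of the four myosin fractions; transitions conserve the
#' total exactly. Tone is the attached-bridge readout
#' `(AMp + w_am AM) / tone_norm`, normalised so full calcium activation
#' gives tone 1.
#'
#' @param myo Named vector (M, Mp, AMp, AM) summing to 1.
#' @param ca,no Calcium (nM) and NO (AU).
#' @param dt Step (s).
#' @param params A [cellular_params()].
#' @param kh Hill midpoint (nM).
#' @return List with `myo` (updated fractions) and `tone` in \[0, ~1\].
#' @export
crossbridge_step <- function(myo, ca, no = 0, dt = 1e-3,
                             params = cellular_params(), kh = 160) {
  r <- xb_rates(ca, no, params, kh)
  k1 <- r$k1; k2 <- r$k_mlcp
  M <- myo[[1]]; Mp <- myo[[2]]; AMp <- myo[[3]]; AM <- myo[[4]]
  dM <- -k1 * M + k2 * Mp + params$k7 * AM
  dMp <- k1 * M - (k2 + params$k3) * Mp + params$k4 * AMp
  dAMp <- params$k3 * Mp - (params$k4 + k2) * AMp + k1 * AM
  dAM <- k2 * AMp - (k1 + params$k7) * AM
  myo <- c(M + dt * dM, Mp + dt * dMp, AMp + dt * dAMp, AM + dt * dAM)
  names(myo) <- c("M", "Mp", "AMp", "AM")
  list(myo = myo, tone = tone_readout(myo, params))
}

#' @rdname crossbridge_step
#' @export
tone_readout <- function(myo, params = cellular_params()) {
  ss <- xb_steady_state(1e6, 0, params, kh = 160)
  (myo[[3]] + params$w_am * myo[[4]]) / (ss[[3]] + params$w_am * ss[[4]])
}

# cached normaliser used in hot loops
.tone_norm <- function(params) {
  ss <- xb_steady_state(1e6, 0, params, kh = 160)
  ss[[3]] + params$w_am * ss[[4]]
}

#' Passive and total diameter of a cellular segment
#'
#' Passive distension
#' `D_pd = 0.9 d_active_max (1 + alpha_c (1 - exp(-K_pd WS)))` with
#' `alpha_c` fixed so the saturated passive diameter equals
#' `passive_ratio x d_active_max` (about 130%); the total diameter
#' subtracts the active constriction
#' `c_tone x contractility x tone x d_active_max`, with `c_tone` calibrated
#' so that full tone at saturated passive distension yields the maximal
#' myogenic tone (about 42% below passive) for the reference segment.
#'
#' @param tone Wall tone in \[0, 1\].
#' @param WS Wall stress (mmHg).
#' @param contractility Relative contractility index of the segment.
#' @param d_active_max Maximal active diameter (um).
#' @param params A [cellular_params()].
#' @return Diameter (um).
#' @export
segment_diameter <- function(tone, WS, contractility, d_active_max,
                             params = cellular_params()) {
  stopifnot(all(tone >= 0))
  d <- passive_diameter(WS, d_active_max, params) -
    .c_tone(params) * contractility * tone * d_active_max
  if (any(d <= 0)) abort("Active constriction produced a non-positive diameter.")
  d
}

#' @rdname segment_diameter
#' @export
passive_diameter <- function(WS, d_active_max, params = cellular_params()) {
  if (any(WS < 0)) abort("Wall stress must be non-negative.")
  alpha_c <- params$passive_ratio / 0.9 - 1
  0.9 * d_active_max * (1 + alpha_c * (1 - exp(-params$K_pd * WS)))
}

# tone coefficient: full tone at saturated passive distension gives mt_max
# below passive for the reference contractility (250 um depth)
.c_tone <- function(params) {
  ci_ref <- 1 - 0.2 * 255 / 840
  params$mt_max * params$passive_ratio / ci_ref
}

#' Myogenic tone of a passive/active diameter pair
#'
#' `MT = (D_passive - D_active) / D_passive * 100`.
#'
#' @param d_passive,d_active Diameters (um).
#' @return Percent.
#' @export
myogenic_tone_pct <- function(d_passive, d_active) {
  (d_passive - d_active) / d_passive * 100
}

#' Per-segment calibration of the cellular model
#'
#' Implements the autoregulation-anchoring step of the workflow: for each
#' requested segment, the sigmoidal transfer functions are centred on the
#' segment's baseline wall stress at the reference arterial pressure (the
#' maximal-active-diameter state at ABNP = 60 mmHg), the depolarising
#' conductance is solved so the membrane balances at `v_base`, the VOCC
#' midpoint so calcium balances at `ca_base`, and the MLCK Hill midpoint so
#' the crossbridge steady state reproduces the segment's baseline diameter.
#'
#' @param net A `vd_network`.
#' @param segment_ids Segments to calibrate (default: all PA segments).
#' @param params A [cellular_params()].
#' @param abnp,vbnp Reference boundary pressures (mmHg).
#' @param stress_max Optional precomputed [record_max_stresses()] result.
#' @return A tibble of class `vd_cell_cal`: one row per segment with the
#'   anchored transfer-function midpoints, conductances and Hill midpoints.
#' @export
calibrate_cellular <- function(net, segment_ids = NULL,
                               params = cellular_params(),
                               abnp = 60, vbnp = 10, stress_max = NULL) {
  sg <- net$segments
  segment_ids <- segment_ids %||% sg$id[sg$class == "PA"]
  ix <- match(segment_ids, sg$id)
  if (anyNA(ix)) abort("Unknown segment ids in `segment_ids`.")
  mx <- stress_max %||% record_max_stresses(net, vbnp = vbnp)
  D0 <- ifelse(sg$is_arteriolar, sg$d_active_max, sg$diameter)
  hs <- solve_pressures(net, D0, abnp = abnp, vbnp = vbnp)

  dmax <- sg$d_active_max[ix]
  h <- sg$wall_thickness[ix]
  ci <- sg$contractility[ix]
  ip0 <- hs$segments$IP[ix]
  wss0 <- hs$segments$WSS[ix]
  wsmax <- mx$WS_max[ix]
  wssmax <- mx$WSS_max[ix]
  ws0 <- ip0 * dmax / h
  x0 <- ws0 / wsmax

  ek <- nernst_k(params$kex_smc0, params$k_in)
  ek_e <- nernst_k(params$kex_ec0, params$k_in)
  vb <- params$v_base
  rect <- .kir_rect(vb, ek, params$kir_rect_min)
  gk0 <- params$g_kir_smc * 0.5 * rect +
    params$g_kv * sigmoid01(vb, 0.14, -25) +
    params$g_bk * sigmoid01(vb, 0.1, -20)
  # EC baseline potential given the SMC at v_base (no flow through MGJ loop
  # is not required; the pair equilibrates jointly)
  kop_ec0 <- wss_to_kir_op_ec(wss0, wssmax, params)
  gke0 <- params$g_kir_ec * kop_ec0 * .kir_rect(vb, ek_e, params$kir_rect_min)
  vec0 <- (gke0 * ek_e + params$g_mgj_ec * vb) / (gke0 + params$g_mgj_ec)
  # depolarising conductance balancing the SMC membrane at v_base
  gd0 <- (gk0 * (ek - vb) + params$g_mgj * (vec0 - vb)) / (vb - params$e_dep)
  if (any(gd0 <= 0)) abort("Calibration failed: non-positive depolarising conductance.")
  vca_mid <- vb + log(params$ca_range / (params$ca_base - params$ca_min) - 1) / params$vca_k

  dpd0 <- passive_diameter(ws0, dmax, params)
  tone0 <- (dpd0 - dmax) / (.c_tone(params) * ci * dmax)
  if (any(tone0 <= 0 | tone0 >= 1)) {
    abort("Calibration failed: baseline tone outside (0, 1).")
  }
  tn <- .tone_norm(params)
  kh <- purrr::map_dbl(tone0, function(t0) {
    uniroot(function(kh) {
      ss <- xb_steady_state(params$ca_base, 0, params, kh)
      (ss[[3]] + params$w_am * ss[[4]]) / tn - t0
    }, c(10, 5000))$root
  })
  structure(tibble(segment_id = segment_ids, d_active_max = dmax,
                   wall_thickness = h, contractility = ci,
                   cortical_depth = sg$cortical_depth[ix],
                   IP0 = ip0, WS0 = ws0, WSS0 = wss0,
                   WS_max = wsmax, WSS_max = wssmax,
                   x0 = x0, gd0 = gd0, vec0 = vec0, vca_mid = vca_mid,
                   tone0 = tone0, kh = kh),
            class = c("vd_cell_cal", class(tibble())))
}

# ---- internal vectorised integrator core -------------------------------

# state: list of equal-length vectors; cal: vd_cell_cal rows aligned with it
.cell_state_init <- function(cal, params) {
  n <- nrow(cal)
  myo <- t(vapply(seq_len(n), function(i) {
    xb_steady_state(params$ca_base, 0, params, cal$kh[i])
  }, numeric(4)))
  ek0 <- nernst_k(params$kex_smc0, params$k_in)
  list(m = rep(0.5, n), kop = rep(0.5, n),
       v = rep(params$v_base, n), vec = cal$vec0,
       rect = rep(.kir_rect(params$v_base, ek0, params$kir_rect_min), n),
       ca = rep(params$ca_base, n), caglu = rep(0, n),
       myo = myo, tone = cal$tone0,
       D = cal$d_active_max)
}

# advance the coupled cellular states over one hemodynamic window
# ip, wss: vectors; med: list of vectors NO, glu, kex_smc, kex_ec (levels
# during this window); adj: 0/1 coupling matrix over segments (or NULL)
.cell_advance <- function(st, cal, params, ip, wss, med, n_sub, adj = NULL) {
  dt <- params$dt
  tn <- .tone_norm(params)
  ct <- .c_tone(params)
  alpha_c <- params$passive_ratio / 0.9 - 1
  kex <- params$kex_smc0 + med$kex_smc
  kex_e <- params$kex_ec0 + med$kex_ec
  ek <- nernst_k(kex, params$k_in)
  ek_e <- nernst_k(kex_e, params$k_in)
  kir_kex <- sqrt(kex / params$kex_smc0)
  kir_kex_e <- sqrt(kex_e / params$kex_ec0)
  kop_ec <- wss_to_kir_op_ec(pmax(wss, 0), cal$WSS_max, params)
  deg <- if (!is.null(adj)) as.numeric(Matrix::rowSums(adj)) else 0
  m <- st$m; kop <- st$kop; v <- st$v; vec <- st$vec; ca <- st$ca
  caglu <- st$caglu; myo <- st$myo; D <- st$D
  rect <- st$rect
  h <- cal$wall_thickness; dmax <- cal$d_active_max
  k3 <- params$k3; k4 <- params$k4; k7 <- params$k7
  for (s in seq_len(n_sub)) {
    ws <- pmax(ip * D / h, 0)
    x <- ws / cal$WS_max
    starget <- sigmoid01(x, params$sig_k, cal$x0)
    m <- m + (starget - m) * dt / params$tau_mct
    kop <- kop + ((1 - starget) - kop) * dt / params$tau_mct
    gd <- cal$gd0 * (2 * m)^params$mech_gain
    rect <- rect + (.kir_rect(v, ek, params$kir_rect_min) - rect) *
      dt / params$tau_rect
    gkir <- params$g_kir_smc * kop * kir_kex * rect
    gk <- gkir + params$g_kv * sigmoid01(v, 0.14, -25) +
      params$g_bk * sigmoid01(v, 0.1, -20) *
        (1 + params$b_glu * caglu + params$b_no * med$NO)
    num <- gd * params$e_dep + gk * ek + params$g_mgj * vec
    den <- gd + gk + params$g_mgj
    if (!is.null(adj)) {
      num <- num + params$g_gap * as.numeric(adj %*% v)
      den <- den + params$g_gap * deg
    }
    v <- v + (num / den - v) * dt / params$tau_vm
    gke <- params$g_kir_ec * kop_ec * kir_kex_e *
      .kir_rect(vec, ek_e, params$kir_rect_min)
    nume <- gke * ek_e + params$g_mgj_ec * v
    dene <- gke + params$g_mgj_ec
    if (!is.null(adj)) {
      nume <- nume + params$g_gap_ec * as.numeric(adj %*% vec)
      dene <- dene + params$g_gap_ec * deg
    }
    vec <- vec + (nume / dene - vec) * dt / params$tau_ec
    cainf <- params$ca_min + params$ca_range * sigmoid01(v, params$vca_k, cal$vca_mid)
    tau_ca <- ifelse(cainf > ca, params$tau_ca_rise, params$tau_ca_fall)
    ca <- ca + (cainf - ca) * dt / tau_ca
    caglu <- caglu + (params$glu_scale * med$glu - caglu) * dt / params$tau_glu
    k1 <- params$k1max * ca^params$hill_n / (ca^params$hill_n + cal$kh^params$hill_n)
    k2 <- params$k2 * (1 + params$beta_no * med$NO)
    M <- myo[, 1]; Mp <- myo[, 2]; AMp <- myo[, 3]; AM <- myo[, 4]
    myo[, 1] <- M + dt * (-k1 * M + k2 * Mp + k7 * AM)
    myo[, 2] <- Mp + dt * (k1 * M - (k2 + k3) * Mp + k4 * AMp)
    myo[, 3] <- AMp + dt * (k3 * Mp - (k4 + k2) * AMp + k1 * AM)
    myo[, 4] <- AM + dt * (k2 * AMp - (k1 + k7) * AM)
    tone <- (myo[, 3] + params$w_am * myo[, 4]) / tn
    dpd <- 0.9 * dmax * (1 + alpha_c * (1 - exp(-params$K_pd * ws)))
    D <- dpd - ct * cal$contractility * pmax(tone, 0) * dmax
    if (any(!is.finite(D)) || any(D <= 0)) {
      abort("Cellular integration diverged (non-positive or non-finite diameter).")
    }
  }
  list(m = m, kop = kop, v = v, vec = vec, rect = rect, ca = ca,
       caglu = caglu, myo = myo, tone = tone, D = D)
}

# isolated-segment steady state at fixed IP (no flow unless wss given)
.cell_steady <- function(cal_row, params, ip, wss = 0, med = NULL,
                         tone_clamp = NULL, inhibit = NULL,
                         iter = 400, relax = 0.25) {
  med <- med %||% list(NO = 0, glu = 0, kex_smc = 0, kex_ec = 0)
  inhibit <- inhibit %||% c(dep = 1, kir = 1, kv = 1, bk = 1)
  dmax <- cal_row$d_active_max
  h <- cal_row$wall_thickness
  kex <- params$kex_smc0 + med$kex_smc
  kex_e <- params$kex_ec0 + med$kex_ec
  ek <- nernst_k(kex, params$k_in)
  ek_e <- nernst_k(kex_e, params$k_in)
  kop_ec <- wss_to_kir_op_ec(max(wss, 0), cal_row$WSS_max, params)
  tn <- .tone_norm(params)
  ct <- .c_tone(params)
  D <- dmax
  for (i in seq_len(iter)) {
    ws <- max(ip * D / h, 0)
    x <- ws / cal_row$WS_max
    m <- sigmoid01(x, params$sig_k, cal_row$x0)
    kop <- 1 - m
    gd <- inhibit[["dep"]] * cal_row$gd0 * (2 * m)^params$mech_gain
    # solve the SMC/EC potential pair at these gatings
    v <- params$v_base
    vec <- cal_row$vec0
    for (j in 1:60) {
      gkir <- inhibit[["kir"]] * params$g_kir_smc * kop *
        sqrt(kex / params$kex_smc0) * .kir_rect(v, ek, params$kir_rect_min)
      gk <- gkir + inhibit[["kv"]] * params$g_kv * sigmoid01(v, 0.14, -25) +
        inhibit[["bk"]] * params$g_bk * sigmoid01(v, 0.1, -20) *
          (1 + params$b_glu * params$glu_scale * med$glu + params$b_no * med$NO)
      gke <- params$g_kir_ec * kop_ec * sqrt(kex_e / params$kex_ec0) *
        .kir_rect(vec, ek_e, params$kir_rect_min)
      v_new <- (gd * params$e_dep + gk * ek + params$g_mgj * vec) /
        (gd + gk + params$g_mgj)
      vec_new <- (gke * ek_e + params$g_mgj_ec * v) / (gke + params$g_mgj_ec)
      if (abs(v_new - v) < 1e-10 && abs(vec_new - vec) < 1e-10) break
      v <- v + 0.5 * (v_new - v); vec <- vec + 0.5 * (vec_new - vec)
    }
    ca <- params$ca_min + params$ca_range * sigmoid01(v, params$vca_k, cal_row$vca_mid)
    tone <- if (!is.null(tone_clamp)) tone_clamp else {
      ss <- xb_steady_state(ca, med$NO, params, cal_row$kh)
      (ss[[3]] + params$w_am * ss[[4]]) / tn
    }
    dpd <- passive_diameter(ws, dmax, params)
    D_new <- dpd - ct * cal_row$contractility * tone * dmax
    if (D_new <= 0) D_new <- 0.05 * dmax
    if (abs(D_new - D) < 1e-10) break
    D <- D + relax * (D_new - D)
  }
  list(D = D, v = v, vec = vec, ca = ca, tone = tone, ws = ws)
}
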