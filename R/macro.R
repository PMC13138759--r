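#' Parameters of the macro-scale arteriolar segment model
#'
#' The macro model drives each arteriolar segment's diameter from two
#' components: a myogenic-response (MR) part proportional to the deviation
#' of the segment's wall stress `MR_D` seconds earlier from its baseline
#' (`WS_avg`), converted to a membrane potential through the myogenic
#' response factor `MR_F` and electrically smoothed across neighbouring
#' segments; and a passive-distension (PD) part, a saturating function of
#' the real-time wall stress. The committed diameter change per main step is
#' rate-limited to `DR_dilation` (fraction/s) upward and `DR_constriction`
#' downward.
#'
#' @param MR_D Myogenic response delay (s).
#' @param MR_F Myogenic response factor (mV per mmHg of WS deviation).
#' @param RC Coupling time constant of the inner electrical loop (s).
#' @param dt1 Main (hemodynamic/vasodynamic) time step (s).
#' @param dt2 Inner coupling time step (s); must satisfy
#'   `dt2 / RC * max_degree < 1` for stability.
#' @param alpha Passive distensibility amplitude (dimensionless).
#' @param K Passive distension rate constant (per mmHg).
#' @param V_baseline Baseline membrane potential (mV).
#' @param DR_dilation,DR_constriction Maximum allowable fractional diameter
#'   change rates (per s).
#' @param NMR_Inh Neuronal myogenic-response inhibition factor (um
#'   equivalent per unit of normalised gamma-band signal).
#' @param nvc_lag Lag between neural activity and its vascular effect (s).
#' @param mV_to_um Conversion from membrane-potential deviation to diameter
#'   (um/mV); the model treats 1 mV as 1 um.
#' @param coupling_tol Inner-loop convergence tolerance (mV per inner step).
#' @return A list of class `vd_macro_params`.
#' @export
macro_params <- function(MR_D = 5, MR_F = 19e-3, RC = 1e-3, dt1 = 0.2,
                         dt2 = 1e-4, alpha = 0.5, K = 3e-3,
                         V_baseline = -45, DR_dilation = 0.15,
                         DR_constriction = 0.075, NMR_Inh = 10,
                         nvc_lag = 1.9, mV_to_um = 1, coupling_tol = 1e-6) {
  stopifnot(MR_D >= 0, RC > 0, dt1 > 0, dt2 > 0, dt2 < dt1,
            DR_dilation > 0, DR_constriction > 0, alpha > 0, K > 0)
  if (dt2 >= RC) abort("`dt2` must be smaller than the coupling time constant `RC`.")
  structure(list(MR_D = MR_D, MR_F = MR_F, RC = RC, dt1 = dt1, dt2 = dt2,
                 alpha = alpha, K = K, V_baseline = V_baseline,
                 DR_dilation = DR_dilation, DR_constriction = DR_constriction,
                 NMR_Inh = NMR_Inh, nvc_lag = nvc_lag, mV_to_um = mV_to_um,
                 coupling_tol = coupling_tol),
            class = "vd_macro_params")
}

#' Baseline wall stress of the arteriolar segments
#'
#' Computes the frozen baseline `WS_avg = IP D / h` from a hemodynamic state
#' (normally the autoregulated state at ABNP = 60 mmHg, where diameters
#' equal the maximal active diameters). The simulation's delayed
#' myogenic feedback measures deviations from this vector; it is computed
#' once at initialisation and never re-baselined.
#'
#' @param net A `vd_network`.
#' @param hemo A [solve_pressures()] result for the initial state.
#' @return A tibble `segment_id`, `WS_avg` (mmHg) over arteriolar segments.
#' @export
init_ws_avg <- function(net, hemo) {
  sg <- net$segments
  art <- sg$is_arteriolar
  tibble(segment_id = sg$id[art], WS_avg = hemo$segments$WS[art])
}

#' Delayed myogenic membrane potential
#'
#' `V_init = V_baseline + MR_F (WS_delayed - WS_avg)`: the uncoupled
#' membrane potential of each arteriolar segment, driven by the wall stress
#' from `MR_D` seconds earlier. Before the first `MR_D` seconds the history
#' is pre-filled with `WS_avg`, so the simulation starts at baseline
#' potential.
#'
#' @param ws_delayed Wall stress `MR_D` seconds ago (mmHg).
#' @param ws_avg Baseline wall stress (mmHg).
#' @param params A [macro_params()].
#' @return Membrane potential(s) in mV.
#' @export
delayed_v_init <- function(ws_delayed, ws_avg, params = macro_params()) {
  params$V_baseline + params$MR_F * (ws_delayed - ws_avg)
}

#' Electrical coupling of segment membrane potentials
#'
#' Smooths membrane potentials across the arteriolar coupling graph by the
#' resistive-capacitive inner loop: repeatedly
#' `V <- V + (dt2/RC) * sum_neighbours(V_nb - V)` until the largest change
#' per inner step falls below `coupling_tol` or the inner loop has covered
#' one main step (`dt1/dt2` iterations). The iteration conserves the mean
#' potential on degree-uniform graphs.
#'
#' @param v_init Vector of uncoupled potentials (mV).
#' @param adjacency Symmetric sparse adjacency over the same segments (see
#'   [arteriolar_coupling()]).
#' @param params A [macro_params()].
#' @return Vector of coupled potentials `V_final` (mV).
#' @export
couple_potentials <- function(v_init, adjacency, params = macro_params()) {
  r <- params$dt2 / params$RC
  deg <- Matrix::rowSums(adjacency)
  if (length(deg) && r * max(deg) >= 1) {
    abort(sprintf(paste0("Coupling iteration unstable: dt2/RC * max_degree = ",
                         "%.3g >= 1; reduce dt2 or increase RC."),
                  r * max(deg)))
  }
  n_steps <- round(params$dt1 / params$dt2)
  v <- v_init
  for (j in seq_len(n_steps)) {
    dv <- r * as.numeric(adjacency %*% v - deg * v)
    v <- v + dv
    if (!all(is.finite(v))) {
      abort("Coupling iteration diverged (non-finite potentials).")
    }
    if (max(abs(dv)) < params$coupling_tol) break
  }
  v
}

#' Dense propagator equivalent to the inner coupling loop
#'
#' Precomputes `M^k` with `M = I + (dt2/RC)(A - deg)` and
#' `k = dt1/dt2`, so the network engine can apply the full inner loop as a
#' single dense matrix-vector product per main step. Numerically equivalent
#' to [couple_potentials()] when the loop does not exit early (on the
#' default 1009-segment network it never does).
#'
#' @param adjacency Symmetric sparse adjacency.
#' @param params A [macro_params()].
#' @return A dense matrix.
#' @export
coupling_propagator <- function(adjacency, params = macro_params()) {
  r <- params$dt2 / params$RC
  deg <- Matrix::rowSums(adjacency)
  if (length(deg) && r * max(deg) >= 1) {
    abort(sprintf("Coupling propagator unstable: dt2/RC * max_degree = %.3g >= 1.",
                  r * max(deg)))
  }
  M <- as.matrix(Diagonal(nrow(adjacency)) + r * (adjacency - Diagonal(x = deg)))
  k <- round(params$dt1 / params$dt2)
  P <- diag(nrow(M))
  while (k > 0) {
    if (k %% 2 == 1) P <- P %*% M
    M <- M %*% M
    k <- k %/% 2
  }
  P
}

#' Myogenic-response component of the diameter
#'
#' `D_MR = (V_baseline - V_final) * mV_to_um`: negative (constricting) when
#' the segment is depolarised above baseline.
#'
#' @param v_final Coupled membrane potential (mV).
#' @param params A [macro_params()].
#' @return um.
#' @export
compute_d_mr <- function(v_final, params = macro_params()) {
  (params$V_baseline - v_final) * params$mV_to_um
}

#' Passive-distension component of the diameter
#'
#' `D_PD = D_WSmin (1 + alpha (1 - exp(-K WS)))`, a saturating distension
#' of the unpressurised diameter `D_WSmin = 0.9 d_active_max`, bounded in
#' `[D_WSmin, D_WSmin (1 + alpha))` and monotone in WS.
#'
#' @param ws Real-time wall stress (mmHg), non-negative.
#' @param d_ws_min Unpressurised diameter (um).
#' @param params A [macro_params()].
#' @return um.
#' @export
compute_d_pd <- function(ws, d_ws_min, params = macro_params()) {
  if (any(ws < 0)) abort("Wall stress must be non-negative.")
  d_ws_min * (1 + params$alpha * (1 - exp(-params$K * ws)))
}

#' Neurogenic modulation of the myogenic response
#'
#' Applies the lagged, range-normalised gamma-band drive to the myogenic
#' component: inhibition `D_MR' = D_MR - NMR_Inh * GB` and damping by the
#' smoothed signal, `contribution = D_MR' * (1 - GB_S)` (the damping factor
#' models the slowly decaying effect of neuronally produced NO).
#'
#' @param d_mr Myogenic component (um).
#' @param gb Range-normalised gamma-band signal, lagged by `nvc_lag`, in
#'   \[0, 1\].
#' @param gb_s Smoothed, lagged gamma-band signal in \[0, 1\].
#' @param params A [macro_params()].
#' @return A list with `d_mr` (inhibited component, um) and `damping`
#'   (multiplier in \[0, 1\]).
#' @export
apply_nvc_modulation <- function(d_mr, gb, gb_s, params = macro_params()) {
  if (any(gb < 0 | gb > 1) || any(gb_s < 0 | gb_s > 1)) {
    abort("Gamma-band signals must be range-normalised to [0, 1].")
  }
  list(d_mr = d_mr - params$NMR_Inh * gb, damping = 1 - gb_s)
}

#' Rate-limited diameter update
#'
#' Clips the candidate diameter (`D_PD` plus modulated `D_MR`) so that the
#' change from the previously committed diameter respects the maximal
#' dilation and constriction rates.
#'
#' @param d_candidate Candidate diameter (um).
#' @param d_prev Previously committed diameter (um).
#' @param params A [macro_params()].
#' @return The committed diameter (um).
#' @export
update_diameter <- function(d_candidate, d_prev, params = macro_params()) {
  if (any(d_prev <= 0)) abort("`d_prev` must be positive.")
  up <- d_prev * (1 + params$DR_dilation * params$dt1)
  dn <- d_prev * (1 - params$DR_constriction * params$dt1)
  d <- pmin(pmax(d_candidate, dn), up)
  if (any(d <= 0)) abort("Diameter update produced a non-positive diameter.")
  d
}
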