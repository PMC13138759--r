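#' Simulate network vasomotion with the macro-scale segment model
#'
#' Runs the coupled hemodynamic-vasodynamic loop on a cerebrovascular
#' network. Each main step (`dt1`): (1) steady-state pressure solve with the
#' current diameters; (2) wall stress per arteriolar segment; (3) delayed
#' myogenic membrane potential from the wall-stress history; (4) inner
#' electrical-coupling loop across adjacent segments; (5) passive-distension
#' and myogenic diameter components (optionally modulated by a gamma-band
#' drive and astrocytic events); (6) rate-limited diameter commit.
#' Initial diameters are the maximal active diameters and the wall-stress
#' baseline `WS_avg` is frozen from the initial state, so the simulation
#' starts at baseline membrane potential and the off-equilibrium passive
#' distension kicks off the oscillation. The run is deterministic.
#'
#' @param net A `vd_network`.
#' @param params A [macro_params()].
#' @param duration Simulated time (s).
#' @param abnp,vbnp Boundary pressures (mmHg).
#' @param record Which segments to record in full (all channels):
#'   `"pa10"` (all segments of the first ten PAs, the default),
#'   `"pa"` (all PA segments), `"arteriolar"`, or a character vector of
#'   segment ids.
#' @param active Segments carrying the active macro model: `"arteriolar"`
#'   (default) or a character vector of segment ids (e.g. one PA only; all
#'   other segments keep fixed diameters).
#' @param gamma Optional gamma-band drive created by [normalize_and_smooth()]
#'   (or [synthetic_gamma()] piped through it); applied globally to all
#'   active segments with lag `params$nvc_lag` per the functional-hyperemia
#'   variant of the model.
#' @param astro Optional [astro_params()] enabling constriction-triggered
#'   astrocytic dilation events.
#' @param freeze_pd_at Time (s) after which the passive-distension component
#'   is held constant (demonstrates oscillation damping); `Inf` disables.
#' @param steady_window Length (s) of the terminal window used for the
#'   per-segment summary statistics.
#' @param visc A [viscosity_model()].
#' @return A `vd_sim` object: list with `trace` (long tibble `time`,
#'   `segment_id`, `D`, `D_MR`, `D_PD`, `V`, `WS`), `summary` (per-segment
#'   steady-window statistics for all arteriolar segments), `events`
#'   (astrocytic event log), `params`, and run metadata.
#' @export
simulate_vasomotion <- function(net, params = macro_params(), duration = 600,
                                abnp = 60, vbnp = 10,
                                record = "pa10", active = "arteriolar",
                                gamma = NULL, astro = NULL,
                                freeze_pd_at = Inf, steady_window = 200,
                                visc = viscosity_model()) {
  if (freeze_pd_at < 0) abort("`freeze_pd_at` must be non-negative (simulation time).")
  sg <- net$segments
  art <- which(sg$is_arteriolar)
  nA <- length(art)
  ids_art <- sg$id[art]

  cp <- arteriolar_coupling(net)
  prop <- coupling_propagator(cp$adjacency, params)

  dmax <- sg$d_active_max[art]
  h <- sg$wall_thickness[art]
  d_ws_min <- 0.9 * dmax

  act <- if (identical(active, "arteriolar")) rep(TRUE, nA) else ids_art %in% active
  rec_ids <- switch(paste0(record[1]),
    pa10 = ids_art[grepl("^PA(0[1-9]|10)_", ids_art)],
    pa = ids_art[startsWith(ids_art, "PA")],
    arteriolar = ids_art,
    intersect(record, ids_art))
  rix <- match(rec_ids, ids_art)
  nR <- length(rix)

  # static hemodynamic structures
  ix <- .hemo_index(net)
  mu <- apparent_viscosity(visc, sg$diameter)
  gcoef <- pi * .QCONV / (128 * mu * sg$length)  # g = gcoef * D^4 (constant-mu fast path)
  const_mu <- visc$mode == "constant"
  pb <- numeric(ix$n); pb[ix$abn] <- abnp; pb[ix$vbn] <- vbnp
  bnd <- c(ix$abn, ix$vbn)
  solve_ip <- function(D_all) {
    g <- if (const_mu) gcoef * D_all^4 else
      segment_conductance(D_all, sg$length, visc)
    A <- sparseMatrix(i = c(ix$ia, ix$ib, ix$ia, ix$ib),
                      j = c(ix$ib, ix$ia, ix$ia, ix$ib),
                      x = c(-g, -g, g, g), dims = c(ix$n, ix$n))
    p <- pb
    p[ix$int] <- as.numeric(solve(A[ix$int, ix$int], -(A[ix$int, bnd] %*% pb[bnd])))
    (p[ix$ia] + p[ix$ib]) / 2
  }

  dt1 <- params$dt1
  nstep <- round(duration / dt1)
  ndel <- max(1L, round(params$MR_D / dt1))
  nlag_gb <- round(params$nvc_lag / dt1)

  D_all <- sg$d_active_max  # autoregulated initial state (microvessels keep diameter)
  D_all[-art] <- sg$diameter[-art]
  IP <- solve_ip(D_all)
  ws_avg <- IP[art] * D_all[art] / h
  ws_hist <- matrix(rep(ws_avg, ndel), nrow = ndel, byrow = TRUE)
  Dprev <- D_all[art]

  # gamma-band drive resampled onto the step grid, lagged
  gb_series <- gb_s_series <- NULL
  if (!is.null(gamma)) {
    tg <- seq_len(nstep) * dt1 - params$nvc_lag
    gb_series <- approx(gamma$t, gamma$gb_norm, xout = tg, rule = 2)$y
    gb_series[tg < min(gamma$t)] <- 0
    gb_s_series <- approx(gamma$t, gamma$gb_s, xout = tg, rule = 2)$y
    gb_s_series[tg < min(gamma$t)] <- 0
  }

  # astro state
  astro_on <- !is.null(astro)
  if (astro_on) {
    rate_ema <- numeric(nA)
    ema_a <- dt1 / max(astro$rate_smooth, dt1)
    last_evt <- rep(-Inf, nA)
    evt_t <- numeric(0); evt_id <- character(0)
  }

  recD <- matrix(NA_real_, nstep, nR)
  recMR <- matrix(NA_real_, nstep, nR)
  recPD <- matrix(NA_real_, nstep, nR)
  recV <- matrix(NA_real_, nstep, nR)
  recWS <- matrix(NA_real_, nstep, nR)

  wsteps <- min(nstep, round(steady_window / dt1))
  sum_steady <- numeric(nA); min_steady <- rep(Inf, nA); max_steady <- rep(-Inf, nA)

  pd_frozen <- NULL
  for (i in seq_len(nstep)) {
    tnow <- i * dt1
    D_all[art] <- Dprev
    IP <- solve_ip(D_all)
    ws <- IP[art] * Dprev / h
    slot <- 1L + (i - 1L) %% ndel
    ws_del <- ws_hist[slot, ]
    v_init <- delayed_v_init(ws_del, ws_avg, params)
    v_fin <- as.numeric(prop %*% v_init)
    d_mr <- compute_d_mr(v_fin, params)
    d_pd <- compute_d_pd(ws, d_ws_min, params)
    if (tnow >= freeze_pd_at) {
      if (is.null(pd_frozen)) pd_frozen <- d_pd
      d_pd <- pd_frozen
    }
    damping <- 1
    if (!is.null(gb_series)) {
      gb_i <- gb_series[i]; gbs_i <- gb_s_series[i]
      mod <- apply_nvc_modulation(d_mr, gb_i, gbs_i, params)
      d_mr <- mod$d_mr
      damping <- mod$damping
    }
    if (astro_on) {
      inh <- (tnow - last_evt) < astro$pulse_duration
      d_mr <- d_mr - astro$k_release_pulse * inh
    }
    cand <- d_pd + d_mr * damping
    Dnew <- update_diameter(cand, Dprev, params)
    Dnew[!act] <- Dprev[!act]
    if (astro_on) {
      rel_rate <- (Dnew - Dprev) / (dt1 * Dprev)
      rate_ema <- rate_ema + ema_a * (rel_rate - rate_ema)
      trig <- act & rate_ema < -astro$constriction_rate_threshold &
        (tnow - last_evt) >= astro$refractory
      if (any(trig)) {
        last_evt[trig] <- tnow
        evt_t <- c(evt_t, rep(tnow, sum(trig)))
        evt_id <- c(evt_id, ids_art[trig])
      }
    }
    ws_hist[slot, ] <- ws
    Dprev <- Dnew
    recD[i, ] <- Dnew[rix]; recMR[i, ] <- d_mr[rix]; recPD[i, ] <- d_pd[rix]
    recV[i, ] <- v_fin[rix]; recWS[i, ] <- ws[rix]
    if (i > nstep - wsteps) {
      sum_steady <- sum_steady + Dnew
      min_steady <- pmin(min_steady, Dnew)
      max_steady <- pmax(max_steady, Dnew)
    }
  }

  tvec <- seq_len(nstep) * dt1
  trace <- tibble(time = rep(tvec, nR),
                  segment_id = rep(rec_ids, each = nstep),
                  D = as.vector(recD), D_MR = as.vector(recMR),
                  D_PD = as.vector(recPD), V = as.vector(recV),
                  WS = as.vector(recWS))
  meanD <- sum_steady / wsteps
  summary <- tibble(segment_id = ids_art,
                    class = sg$class[art],
                    cortical_depth = sg$cortical_depth[art],
                    mean_D = meanD,
                    min_D = min_steady, max_D = max_steady,
                    amplitude_pct = (max_steady - min_steady) / meanD * 100)
  events <- if (astro_on) {
    tibble(time = evt_t, segment_id = evt_id, event = "astro_pulse")
  } else {
    tibble(time = numeric(0), segment_id = character(0), event = character(0))
  }
  structure(list(trace = trace, summary = summary, events = events,
                 params = params, mode = "vasomotion_macro",
                 abnp = abnp, vbnp = vbnp, duration = duration,
                 steady_window = steady_window, ws_avg = ws_avg,
                 record_ids = rec_ids),
            class = "vd_sim")
}

#' @export
print.vd_sim <- function(x, ...) {
  cat("<vd_sim> mode =", x$mode, ";", x$duration, "s;",
      length(x$record_ids), "recorded segments\n")
  invisible(x)
}
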