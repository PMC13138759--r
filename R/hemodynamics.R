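#' Blood viscosity model
#'
#' Either a constant apparent viscosity (default 3 mPa s) or a
#' diameter-dependent in-vitro law of the Pries type,
#' `mu(D) = plasma * (1 + (mu45 - 1) * ((D / (D + d0))^2))`, a smooth
#' monotone approximation capturing the Fahraeus-Lindqvist reduction of
#' apparent viscosity in narrow tubes.
#'
#' @param mode `"constant"` or `"diameter_dependent"`.
#' @param mu_constant Apparent viscosity (mPa s) for the constant mode.
#' @param plasma Plasma viscosity (mPa s), diameter-dependent mode.
#' @param mu45 Relative apparent viscosity at large diameters.
#' @param d0 Half-saturation diameter (um).
#' @return A list of class `vd_viscosity`; call it via [apparent_viscosity()].
#' @export
viscosity_model <- function(mode = c("constant", "diameter_dependent"),
                            mu_constant = 3, plasma = 1.2, mu45 = 2.8,
                            d0 = 10) {
  mode <- match.arg(mode)
  stopifnot(mu_constant > 0, plasma > 0, mu45 > 1, d0 > 0)
  structure(list(mode = mode, mu_constant = mu_constant, plasma = plasma,
                 mu45 = mu45, d0 = d0), class = "vd_viscosity")
}

#' @rdname viscosity_model
#' @param D Diameter(s) in um.
#' @export
apparent_viscosity <- function(visc, D) {
  if (visc$mode == "constant") {
    rep(visc$mu_constant, length(D))
  } else {
    visc$plasma * (1 + (visc$mu45 - 1) * (D / (D + visc$d0))^2)
  }
}

#' Poiseuille conductance of a cylindrical segment
#'
#' `G = pi D^4 / (128 mu(D) L)` expressed in nl/min per mmHg, with `D` and
#' `L` in um and viscosity in mPa s.
#'
#' @param D Diameter (um).
#' @param L Length (um).
#' @param visc A [viscosity_model()].
#' @return Conductance in nl/min per mmHg.
#' @export
segment_conductance <- function(D, L, visc = viscosity_model()) {
  if (any(D <= 0) || any(L <= 0)) abort("`D` and `L` must be positive.")
  mu <- apparent_viscosity(visc, D)
  pi * D^4 * .QCONV / (128 * mu * L)
}

# internal: precompute node indexing for repeated solves on one topology
.hemo_index <- function(net) {
  sg <- net$segments
  ids <- net$nodes$id
  ni <- setNames(seq_along(ids), ids)
  abn <- which(net$nodes$kind == "artery_boundary")
  vbn <- which(net$nodes$kind == "vein_boundary")
  list(ia = unname(ni[sg$node_a]), ib = unname(ni[sg$node_b]),
       n = length(ids), abn = abn, vbn = vbn,
       int = setdiff(seq_along(ids), c(abn, vbn)))
}

#' Steady-state pressure and flow solve on the network
#'
#' Solves the nodal conductance (Kirchhoff) system with Dirichlet conditions
#' at the two boundary nodes, then derives per-segment flow, intravascular
#' pressure (IP, mean of the end-node pressures), circumferential wall
#' stress (WS = IP D / h, Laplace) and wall shear stress
#' (WSS = 32 mu |Q| / (pi D^3), Poiseuille).
#'
#' @param net A `vd_network`.
#' @param diameters Optional named vector of diameters (um) overriding the
#'   network's current diameters; names are segment ids. Unnamed vectors
#'   must match `net$segments` row order.
#' @param abnp,vbnp Boundary pressures (mmHg); default to the values stored
#'   on the network's boundary nodes.
#' @param visc A [viscosity_model()].
#' @param index Internal reusable indexing object; leave `NULL`.
#' @return A list of class `vd_hemo`: `node_pressure` (tibble `node`,
#'   `pressure`), `segments` (tibble `segment_id`, `Q` in nl/min signed
#'   node_a to node_b, `IP` mmHg, `WS` mmHg, `WSS` dyn/cm2).
#' @export
solve_pressures <- function(net, diameters = NULL, abnp = NULL, vbnp = NULL,
                            visc = viscosity_model(), index = NULL) {
  sg <- net$segments
  D <- sg$diameter
  if (!is.null(diameters)) {
    if (!is.null(names(diameters))) {
      ix <- match(names(diameters), sg$id)
      if (anyNA(ix)) abort("Unknown segment ids in `diameters`.")
      D[ix] <- unname(diameters)
    } else {
      stopifnot(length(diameters) == nrow(sg))
      D <- diameters
    }
  }
  if (any(D <= 0)) abort("All diameters must be positive.")
  abnp <- abnp %||% net$nodes$boundary_pressure[net$nodes$kind == "artery_boundary"]
  vbnp <- vbnp %||% net$nodes$boundary_pressure[net$nodes$kind == "vein_boundary"]
  if (abnp <= vbnp) abort("ABNP must exceed VBNP.")
  ix <- index %||% .hemo_index(net)
  g <- segment_conductance(D, sg$length, visc)
  A <- sparseMatrix(i = c(ix$ia, ix$ib, ix$ia, ix$ib),
                    j = c(ix$ib, ix$ia, ix$ia, ix$ib),
                    x = c(-g, -g, g, g), dims = c(ix$n, ix$n))
  pb <- numeric(ix$n); pb[ix$abn] <- abnp; pb[ix$vbn] <- vbnp
  p <- pb
  sol <- tryCatch(
    solve(A[ix$int, ix$int], -(A[ix$int, c(ix$abn, ix$vbn)] %*% pb[c(ix$abn, ix$vbn)])),
    error = function(e) abort(paste0("Pressure solve failed (singular or disconnected system): ",
                                     conditionMessage(e))))
  p[ix$int] <- as.numeric(sol)
  Q <- g * (p[ix$ia] - p[ix$ib])
  IP <- (p[ix$ia] + p[ix$ib]) / 2
  mu <- apparent_viscosity(visc, D)
  WS <- IP * D / sg$wall_thickness
  WSS <- 32 * mu * abs(Q) / (pi * D^3) * .WSSCONV
  structure(list(node_pressure = tibble(node = net$nodes$id, pressure = p),
                 segments = tibble(segment_id = sg$id, D = D, Q = Q, IP = IP,
                                   WS = WS, WSS = WSS),
                 abnp = abnp, vbnp = vbnp),
            class = "vd_hemo")
}

#' @export
print.vd_hemo <- function(x, ...) {
  cat("<vd_hemo> ABNP =", x$abnp, "VBNP =", x$vbnp, "mmHg;",
      nrow(x$segments), "segments\n")
  print(x$segments, n = 5)
  invisible(x)
}

#' Net flow residual at interior nodes
#'
#' Mass conservation check: for every interior node the signed flows of the
#' incident segments must sum to zero (relative to the largest flow).
#'
#' @param net A `vd_network`.
#' @param hemo A [solve_pressures()] result on that network.
#' @return Maximum absolute node residual divided by `max(abs(Q))`.
#' @export
flow_conservation_error <- function(net, hemo) {
  sg <- net$segments
  Q <- hemo$segments$Q
  res <- c(tapply(c(-Q, Q), c(sg$node_a, sg$node_b), sum))
  interior <- net$nodes$id[net$nodes$kind == "interior"]
  max(abs(res[interior])) / max(abs(Q))
}

#' Maximum wall stresses over an arterial-pressure sweep
#'
#' Sweeps the arterial boundary pressure (default 40 to 130 mmHg in
#' 10 mmHg steps) with arteriolar diameters following a linear
#' autoregulation schedule from the maximal active diameter at the lower
#' limit down to `constricted_frac` x that diameter at the upper limit, and
#' records each segment's maximum WS and WSS. These maxima normalise the
#' sigmoidal mechanotransduction transfer functions of the cellular model.
#'
#' @param net A `vd_network`.
#' @param abnp_sweep Pressures (mmHg); must include 130.
#' @param vbnp Venous boundary pressure (mmHg).
#' @param constricted_frac Arteriolar diameter fraction at the top of the
#'   sweep (maximally constricted autoregulated state).
#' @param visc A [viscosity_model()].
#' @return A tibble `segment_id`, `WS_max` (mmHg), `WSS_max` (dyn/cm2).
#' @export
record_max_stresses <- function(net, abnp_sweep = seq(40, 130, by = 10),
                                vbnp = 10, constricted_frac = 0.77,
                                visc = viscosity_model()) {
  if (!any(abs(abnp_sweep - 130) < 1e-9)) {
    abort("`abnp_sweep` must include 130 mmHg, where wall stresses peak.")
  }
  sg <- net$segments
  ix <- .hemo_index(net)
  ws_max <- rep(0, nrow(sg)); wss_max <- rep(0, nrow(sg))
  lo <- min(abnp_sweep); hi <- max(abnp_sweep)
  for (abnp in abnp_sweep) {
    f <- if (hi == lo) constricted_frac else
      1 - (1 - constricted_frac) * (abnp - lo) / (hi - lo)
    D <- ifelse(sg$is_arteriolar, sg$d_active_max * f, sg$diameter)
    hs <- solve_pressures(net, D, abnp = abnp, vbnp = vbnp, visc = visc,
                          index = ix)
    ws_max <- pmax(ws_max, hs$segments$WS)
    wss_max <- pmax(wss_max, hs$segments$WSS)
  }
  tibble(segment_id = sg$id, WS_max = ws_max, WSS_max = wss_max)
}
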