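# shared fixtures, built once per test run
.tenv <- new.env()

tiny_config <- function(...) {
  network_config(n_pa = 2, segments_per_pa = 4, n_pial_segments = 6,
                 pial_segment_length = 100, ...)
}

tiny_network <- function() {
  if (is.null(.tenv$tiny)) .tenv$tiny <- build_network(tiny_config())
  .tenv$tiny
}

default_network <- function() {
  if (is.null(.tenv$full)) .tenv$full <- build_network(network_config())
  .tenv$full
}

default_stress_max <- function() {
  if (is.null(.tenv$mx)) .tenv$mx <- record_max_stresses(default_network())
  .tenv$mx
}

reference_calibration <- function(params = cellular_params()) {
  if (is.null(.tenv$cal)) {
    .tenv$cal <- calibrate_cellular(default_network(), "PA01_09", params,
                                    stress_max = default_stress_max())
  }
  .tenv$cal
}

# independent dense-solver oracle for nodal pressures (plain base R)
dense_pressure_oracle <- function(net, diameters, abnp, vbnp, mu = 3) {
  sg <- net$segments
  ids <- net$nodes$id
  n <- length(ids)
  g <- pi * diameters^4 * (133.322e-15 * 6e13) / (128 * mu * sg$length)
  A <- matrix(0, n, n)
  ia <- match(sg$node_a, ids); ib <- match(sg$node_b, ids)
  for (k in seq_along(g)) {
    A[ia[k], ia[k]] <- A[ia[k], ia[k]] + g[k]
    A[ib[k], ib[k]] <- A[ib[k], ib[k]] + g[k]
    A[ia[k], ib[k]] <- A[ia[k], ib[k]] - g[k]
    A[ib[k], ia[k]] <- A[ib[k], ia[k]] - g[k]
  }
  bnd <- c(which(net$nodes$kind == "artery_boundary"),
           which(net$nodes$kind == "vein_boundary"))
  p <- numeric(n); p[bnd] <- c(abnp, vbnp)
  int <- setdiff(seq_len(n), bnd)
  p[int] <- base::solve(A[int, int], -A[int, bnd] %*% p[bnd])
  setNames(p, ids)
}

# peak indices with a minimal prominence, for cycle counting in tests
prominent_peaks <- function(x, prom) {
  i <- which(diff(sign(diff(x))) < 0) + 1L
  i[vapply(i, function(k) {
    left <- min(x[max(1, k - 150):k]); right <- min(x[k:min(length(x), k + 150)])
    x[k] - max(left, right) >= prom
  }, logical(1))]
}
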