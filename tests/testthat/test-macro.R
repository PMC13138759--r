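test_that("delayed myogenic potential converts wall-stress deviations at MR_F", {
  p <- macro_params()
  expect_equal(delayed_v_init(500, 500, p), -45)
  expect_equal(delayed_v_init(600, 500, p), -43.1)
  expect_equal(delayed_v_init(400, 500, p), -46.9)
})

test_that("baseline wall stress is frozen from the initial hemodynamic state", {
  # D = 17.5 um, IP = 50 mmHg, h = 1.75 um -> WS_avg = 500 mmHg
  nodes <- tibble::tibble(id = c("ABN", "VBN", "m"),
                          kind = c("artery_boundary", "vein_boundary", "interior"),
                          boundary_pressure = c(90, 10, NA))
  segs <- tibble::tibble(id = c("a", "b"), class = "PA",
                         node_a = c("ABN", "m"), node_b = c("m", "VBN"),
                         length = 30, diameter = 17.5, d_active_max = 17.5,
                         wall_thickness = 1.75, cortical_depth = 100,
                         contractility = 1, is_arteriolar = TRUE)
  net <- structure(list(nodes = nodes, segments = segs, config = NULL),
                   class = "vd_network")
  hs <- solve_pressures(net, abnp = 90, vbnp = 10)  # mid node at 50
  ws <- init_ws_avg(net, hs)
  expect_equal(ws$WS_avg, c(70 * 10, 30 * 10))      # IP 70 and 30 per segment
  expect_equal(hs$segments$IP[1] * 17.5 / 1.75, ws$WS_avg[1])
})

test_that("electrical coupling diffuses toward the neighbourhood mean", {
  p <- macro_params()
  # isolated segment untouched
  adj0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(1, 1))
  expect_equal(couple_potentials(-47, adj0, p), -47)
  # a coupled pair converges to its mean and preserves it
  adj <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1)
  v <- couple_potentials(c(-40, -50), adj, p)
  expect_equal(v, c(-45, -45), tolerance = 1e-5)
  expect_equal(mean(v), -45, tolerance = 1e-9)
  # single inner step by hand: dt2/RC = 0.1 moves each end by 0.1 of the gap
  p1 <- macro_params(dt1 = 1.4e-4)  # rounds to a single inner iteration
  expect_equal(couple_potentials(c(-40, -50), adj, p1), c(-41, -49))
  # stability guard names the violated bound
  bad <- macro_params(dt2 = 5e-4, RC = 1e-3)
  star <- Matrix::sparseMatrix(i = c(1, 1, 1, 2, 3, 4), j = c(2, 3, 4, 1, 1, 1),
                               x = 1)
  expect_error(couple_potentials(rep(-45, 4), star, bad), "dt2/RC")
})

test_that("the dense propagator reproduces the iterative coupling loop", {
  net <- tiny_network()
  cp <- arteriolar_coupling(net)
  p <- macro_params()
  p0 <- macro_params(coupling_tol = 0)  # disable early exit for exact equivalence
  P <- coupling_propagator(cp$adjacency, p0)
  set.seed(7)
  v0 <- -45 + rnorm(length(cp$ids))
  expect_equal(as.numeric(P %*% v0), couple_potentials(v0, cp$adjacency, p0),
               tolerance = 1e-8)
  # mean conservation on a degree-uniform graph (a ring)
  n <- 6
  ring <- Matrix::sparseMatrix(i = c(seq_len(n), seq_len(n)),
                               j = c(c(2:n, 1), c(n, 1:(n - 1))), x = 1,
                               dims = c(n, n))
  vr <- couple_potentials(seq(-50, -40, length.out = n), ring, p)
  expect_equal(mean(vr), mean(seq(-50, -40, length.out = n)), tolerance = 1e-9)
})

test_that("diameter components follow their closed forms", {
  p <- macro_params()
  expect_equal(compute_d_mr(-45, p), 0)
  expect_equal(compute_d_mr(-47, p), 2)
  expect_equal(compute_d_mr(-43.1, p), -1.9)
  d0 <- 14.76
  expect_equal(compute_d_pd(0, d0, p), d0)
  expect_equal(compute_d_pd(500, d0, p), d0 * (1 + 0.5 * (1 - exp(-1.5))))
  expect_equal(compute_d_pd(500, d0, p), 20.4933, tolerance = 1e-4)
  expect_lt(compute_d_pd(5000, d0, p), 1.5 * d0)
  ws <- seq(0, 2000, by = 50)
  expect_true(all(diff(compute_d_pd(ws, d0, p)) > 0))
  expect_error(compute_d_pd(-1, d0, p), "non-negative")
})

test_that("neurogenic modulation inhibits and damps the myogenic component", {
  p <- macro_params()
  m0 <- apply_nvc_modulation(2, 0, 0, p)
  expect_equal(m0$d_mr, 2); expect_equal(m0$damping, 1)
  m1 <- apply_nvc_modulation(2, 0.5, 0, p)
  expect_equal(m1$d_mr, -3)
  m2 <- apply_nvc_modulation(2, 0, 1, p)
  expect_equal(m2$damping, 0)  # myogenic contribution fully nulled
  expect_error(apply_nvc_modulation(2, 1.4, 0, p), "range-normalised")
})

test_that("diameter commits are rate-limited against the previous value", {
  p <- macro_params()
  expect_equal(update_diameter(10.1, 10, p), 10.1)
  expect_equal(update_diameter(10.5, 10, p), 10 * (1 + 0.15 * 0.2))  # 10.3
  expect_equal(update_diameter(9.0, 10, p), 10 * (1 - 0.075 * 0.2))  # 9.85
  expect_error(update_diameter(5, -1, p), "positive")
})
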