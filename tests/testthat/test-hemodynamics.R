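test_that("Poiseuille conductance follows the fourth-power law and checked units", {
  v <- viscosity_model()
  g1 <- segment_conductance(10, 30, v)
  expect_equal(segment_conductance(20, 30, v) / g1, 16)
  expect_equal(segment_conductance(10, 60, v) / g1, 0.5)
  # independent SI evaluation for D = 16.4 um, L = 30 um, mu = 3 mPa s
  D <- 16.4e-6; L <- 30e-6; mu <- 3e-3
  g_si <- pi * D^4 / (128 * mu * L)            # m^3/s per Pa
  g_ref <- g_si * 133.322 * (1e12 * 60)  # Pa/mmHg and m^3/s -> nl/min
  expect_equal(segment_conductance(16.4, 30, v), g_ref, tolerance = 1e-12)
  expect_error(segment_conductance(-1, 30, v), "positive")
})

test_that("two equal segments in series split the pressure drop in half", {
  # hand-built 2-segment network: ABN - mid - VBN
  nodes <- tibble::tibble(id = c("ABN", "VBN", "mid"),
                          kind = c("artery_boundary", "vein_boundary", "interior"),
                          boundary_pressure = c(90, 10, NA))
  segs <- tibble::tibble(id = c("s1", "s2"), class = "pial",
                         node_a = c("ABN", "mid"), node_b = c("mid", "VBN"),
                         length = 50, diameter = 12, d_active_max = 12,
                         wall_thickness = 1.2, cortical_depth = 0,
                         contractility = 1, is_arteriolar = TRUE)
  net <- structure(list(nodes = nodes, segments = segs, config = NULL),
                   class = "vd_network")
  hs <- solve_pressures(net, abnp = 90, vbnp = 10)
  expect_equal(hs$node_pressure$pressure[hs$node_pressure$node == "mid"], 50)
  expect_equal(hs$segments$Q[1], hs$segments$Q[2])
})

test_that("pressure solve conserves flow and matches the dense oracle", {
  net <- tiny_network()
  hs <- solve_pressures(net, abnp = 60, vbnp = 10)
  expect_lt(flow_conservation_error(net, hs), 1e-9)
  p_oracle <- dense_pressure_oracle(net, net$segments$diameter, 60, 10)
  expect_equal(hs$node_pressure$pressure,
               unname(p_oracle[hs$node_pressure$node]), tolerance = 1e-9)
  # pressure decreases monotonically along an unbranched PA chain
  sg <- net$segments
  chain <- sg[grepl("^PA01_", sg$id), ]
  p <- setNames(hs$node_pressure$pressure, hs$node_pressure$node)
  along <- c(p[chain$node_a[1]], p[chain$node_b])
  expect_true(all(diff(along) < 0))
  expect_true(all(hs$node_pressure$pressure <= 60 + 1e-9 &
                  hs$node_pressure$pressure >= 10 - 1e-9))
})

test_that("derived stresses follow Laplace and Poiseuille scalings", {
  # WS = IP * D / h: 50 mmHg at D = 16.4, h = 1.64 -> 500 mmHg
  expect_equal(50 * 16.4 / 1.64, 500)
  net <- tiny_network()
  h1 <- solve_pressures(net, abnp = 60, vbnp = 10)
  h2 <- solve_pressures(net, abnp = 110, vbnp = 10)
  i <- match("PA01_02", net$segments$id)
  # WS linear in IP at fixed D, h
  expect_equal(h2$segments$WS[i] / h1$segments$WS[i],
               h2$segments$IP[i] / h1$segments$IP[i], tolerance = 1e-12)
  # WSS ~ Q / D^3 at fixed viscosity
  expect_equal(h1$segments$WSS[i],
               32 * 3 * abs(h1$segments$Q[i]) /
                 (pi * net$segments$diameter[i]^3) * (1e3 / 6),
               tolerance = 1e-9)
})

test_that("stress maxima come from the top of the pressure sweep", {
  net <- tiny_network()
  mx <- record_max_stresses(net)
  one <- record_max_stresses(net, abnp_sweep = 130)
  hs130 <- solve_pressures(net,
                           ifelse(net$segments$is_arteriolar,
                                  net$segments$d_active_max * 0.77,
                                  net$segments$diameter),
                           abnp = 130, vbnp = 10)
  expect_equal(one$WS_max, hs130$segments$WS)
  hs40 <- solve_pressures(net, abnp = 40, vbnp = 10)
  expect_true(all(mx$WS_max >= hs40$segments$WS - 1e-9))
  expect_error(record_max_stresses(net, abnp_sweep = seq(40, 120, 10)), "130")
})

test_that("diameter-dependent viscosity stays positive and monotone", {
  v <- viscosity_model("diameter_dependent")
  mu <- apparent_viscosity(v, c(3, 6, 12, 24, 100))
  expect_true(all(mu > 0))
  expect_true(all(diff(mu) > 0))
  expect_lt(mu[1], apparent_viscosity(viscosity_model(), 3)[1] + 3)
})
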