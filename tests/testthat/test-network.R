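test_that("PA taper interpolates the stated endpoints and rejects out-of-range depths", {
  cfg <- network_config()
  expect_equal(pa_taper_diameter(0, cfg), 18)
  expect_equal(pa_taper_diameter(840, cfg), 12.6)
  expect_equal(pa_taper_diameter(250, cfg), 18 - (18 - 12.6) * 250 / 840)
  expect_equal(round(pa_taper_diameter(250, cfg), 1), 16.4)
  d <- pa_taper_diameter(seq(0, 840, by = 30), cfg)
  expect_true(all(diff(d) < 0))
  expect_error(pa_taper_diameter(-1, cfg), "depth")
  expect_error(pa_taper_diameter(841, cfg), "depth")
})

test_that("default generation satisfies the segment-count identities", {
  net <- default_network()
  sg <- net$segments
  expect_equal(sum(sg$class == "PA"), 30 * 28)
  expect_equal(sum(sg$is_arteriolar), 169 + 30 * 28)
  expect_equal(sum(net$nodes$kind == "artery_boundary"), 1)
  expect_equal(sum(net$nodes$kind == "vein_boundary"), 1)
  # minimal topology: 1 PA, 1 pial segment -> 29 arteriolar segments
  mini <- build_network(network_config(n_pa = 1, n_pial_segments = 1))
  expect_equal(sum(mini$segments$is_arteriolar), 29)
  expect_error(network_config(n_pa = 30, n_pial_segments = 10), "Infeasible")
})

test_that("generated networks respect wall-thickness, taper and contractility invariants", {
  net <- default_network()
  pa <- net$segments[net$segments$class == "PA", ]
  expect_equal(pa$wall_thickness, 0.1 * pa$d_active_max)
  expect_equal(pa$length, rep(30, nrow(pa)))
  for (p in c(1, 17)) {
    chain <- pa[grepl(sprintf("^PA%02d_", p), pa$id), ]
    expect_true(all(diff(chain$diameter) < 0))
    expect_true(all(diff(chain$contractility) <= 0))
  }
  expect_silent(validate_network(net))
})

test_that("arteriolar coupling links exactly the segments sharing a node", {
  net <- tiny_network()
  cp <- arteriolar_coupling(net)
  adj <- cp$adjacency
  expect_true(Matrix::isSymmetric(adj))
  # interior PA segment has two neighbours along its chain
  mid <- which(cp$ids == "PA01_02")
  expect_equal(sum(adj[mid, ]), 2)
  # PA root segment is coupled to its pial parent
  root <- which(cp$ids == "PA01_01")
  nb <- cp$ids[which(adj[root, ] > 0)]
  expect_true(any(startsWith(nb, "P0")))
  # microvessels never appear
  expect_false(any(grepl("^M", cp$ids)))
})

test_that("CSV and GraphML round trips preserve the network", {
  net <- tiny_network()
  for (ext in c("csv", "graphml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_network(net, path)
    back <- read_network(path)
    a <- dplyr::arrange(net$segments, id)
    b <- dplyr::arrange(back$segments, id)
    expect_identical(a$id, b$id)
    expect_identical(a$node_a, b$node_a)
    expect_identical(a$is_arteriolar, b$is_arteriolar)
    for (col in c("length", "diameter", "d_active_max", "wall_thickness",
                  "cortical_depth", "contractility")) {
      expect_equal(a[[col]], b[[col]], tolerance = 1e-9)
    }
    expect_equal(back$nodes$boundary_pressure[back$nodes$kind == "artery_boundary"],
                 net$nodes$boundary_pressure[net$nodes$kind == "artery_boundary"])
  }
})

test_that("malformed network files are rejected", {
  net <- tiny_network()
  path <- withr::local_tempfile(fileext = ".csv")
  write_network(net, path)
  # drop a required column
  lines <- readLines(path)
  broken <- withr::local_tempfile(fileext = ".csv")
  writeLines(gsub('"h_um"', '"h_um_gone"', lines), broken)
  expect_error(read_network(broken), "missing columns")
  # duplicate artery boundary node in GraphML
  gpath <- withr::local_tempfile(fileext = ".graphml")
  bad <- net
  bad$nodes$kind[match("n1", bad$nodes$id)] <- "artery_boundary"
  bad$nodes$boundary_pressure[match("n1", bad$nodes$id)] <- 60
  write_network(bad, gpath)
  expect_error(read_network(gpath), "exactly one")
})
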