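#' Configuration for the default cerebrovascular network
#'
#' Parameters controlling generation of the segmented cerebrovascular graph:
#' a pial arterial tree rooted at the artery boundary node (ABN), `n_pa`
#' penetrating arterioles (PAs) of `segments_per_pa` segments each, and a
#' fixed chain of downstream microvessels (precapillary sphincter, three
#' transition-zone orders, three capillary orders) per PA draining to the
#' vein boundary node (VBN).
#'
#' PA diameters taper linearly with cortical depth from `d_surface` at the
#' pial surface to `d_deep` at the deepest point
#' (`segments_per_pa * pa_segment_length` micrometres down). The pial tree
#' carries the bulk of the pre-arteriolar pressure drop; its taper and
#' segment length are chosen so that, at an arterial boundary pressure of
#' 40 mmHg, the intravascular pressure at 250 um cortical depth falls in the
#' 30-35 mmHg autoregulation anchor range (see the methods vignette).
#'
#' @param n_pa Number of penetrating arterioles.
#' @param segments_per_pa Segments per PA chain.
#' @param pa_segment_length Length of one PA segment (um).
#' @param d_surface,d_deep Maximal active PA diameter at the surface and at
#'   full depth (um); `d_surface > d_deep`.
#' @param n_pial_segments Number of pial segments in the arterial tree.
#' @param pial_d_root,pial_d_leaf Pial diameter taper endpoints (um).
#' @param pial_segment_length Length of one pial segment (um).
#' @param micro Data frame describing the per-PA microvessel chain with
#'   columns `class`, `length`, `diameter`.
#' @param seed Integer seed recorded with the network (generation itself is
#'   deterministic).
#' @return A list of class `vd_network_config`.
#' @export
network_config <- function(n_pa = 30,
                           segments_per_pa = 28,
                           pa_segment_length = 30,
                           d_surface = 18,
                           d_deep = 12.6,
                           n_pial_segments = 169,
                           pial_d_root = 26,
                           pial_d_leaf = 16,
                           pial_segment_length = 400,
                           micro = default_microvessels(),
                           seed = 1L) {
  stopifnot(n_pa >= 1, segments_per_pa >= 1, pa_segment_length > 0,
            n_pial_segments >= 1, pial_segment_length > 0)
  if (d_surface <= d_deep) {
    abort("`d_surface` must exceed `d_deep` (PA diameters taper with depth).")
  }
  if (n_pial_segments < n_pa) {
    abort("Infeasible topology: `n_pial_segments` must be >= `n_pa` so every PA root can attach to a pial segment.")
  }
  structure(list(n_pa = as.integer(n_pa),
                 segments_per_pa = as.integer(segments_per_pa),
                 pa_segment_length = pa_segment_length,
                 d_surface = d_surface, d_deep = d_deep,
                 n_pial_segments = as.integer(n_pial_segments),
                 pial_d_root = pial_d_root, pial_d_leaf = pial_d_leaf,
                 pial_segment_length = pial_segment_length,
                 micro = micro, seed = as.integer(seed)),
            class = "vd_network_config")
}

#' Default downstream microvessel chain per penetrating arteriole
#'
#' One precapillary sphincter, three transition-zone orders and three
#' capillary orders, with fixed diameters (no active wall model). Diameters
#' step down toward the terminal capillary; they set the fixed downstream
#' resistance against which the arteriolar tree autoregulates.
#'
#' @return A tibble with columns `class`, `length` (um) and `diameter` (um).
#' @export
default_microvessels <- function() {
  tibble(class = c("sphincter", "TZ", "TZ", "TZ",
                   "capillary", "capillary", "capillary"),
         length = c(20, 40, 40, 40, 60, 60, 60),
         diameter = c(8.5, 7.5, 7, 6.5, 6.2, 5.8, 5.5))
}

#' Linear diameter taper of a penetrating arteriole
#'
#' Maximal active diameter of a PA at a given cortical depth, interpolating
#' linearly from `d_surface` at depth 0 to `d_deep` at the deepest point of
#' the PA. At the default taper (18 um to 12.6 um over 840 um) a segment at
#' 250 um depth has a maximal active diameter of about 16.4 um.
#'
#' @param depth Cortical depth in um (0 at the surface, positive downward).
#' @param config A [network_config()].
#' @return Diameter in um.
#' @export
#' @examples
#' pa_taper_diameter(c(0, 250, 840), network_config())
pa_taper_diameter <- function(depth, config = network_config()) {
  total <- config$segments_per_pa * config$pa_segment_length
  if (any(depth < 0 | depth > total)) {
    abort(sprintf("`depth` must lie within [0, %g] um (the PA span).", total))
  }
  config$d_surface - (config$d_surface - config$d_deep) * depth / total
}

# balanced binary tree with n leaves; edges returned in BFS order
.pial_tree_edges <- function(n_leaves) {
  from <- integer(0); to <- integer(0); is_leaf <- logical(0)
  nid <- 1L
  queue <- list(list(parent = 1L, n = n_leaves))
  while (length(queue)) {
    it <- queue[[1]]; queue <- queue[-1]
    if (it$n == 1L) {
      nid <- nid + 1L
      from <- c(from, it$parent); to <- c(to, nid); is_leaf <- c(is_leaf, TRUE)
    } else {
      for (nn in c(it$n %/% 2L, it$n - it$n %/% 2L)) {
        nid <- nid + 1L
        from <- c(from, it$parent); to <- c(to, nid); is_leaf <- c(is_leaf, FALSE)
        queue <- c(queue, list(list(parent = nid, n = nn)))
      }
    }
  }
  list(from = from, to = to, is_leaf = is_leaf)
}

#' Generate the default cerebrovascular network
#'
#' Builds the full segmented graph: one artery boundary node (ABN), a pial
#' arterial tree of `n_pial_segments` segments, `n_pa` penetrating arterioles
#' of `segments_per_pa` segments each attached to pial leaves, a fixed
#' microvessel chain per PA, and one vein boundary node (VBN). Pial and PA
#' segments are flagged arteriolar (they carry the active wall models);
#' microvessels are passive fixed-diameter conduits. With defaults the
#' network has 30 x 28 = 840 PA segments and 1009 arteriolar segments in
#' total. Generation is deterministic.
#'
#' Wall thickness is 0.1 x the maximal active diameter; the contractility
#' index decreases linearly with cortical depth along each PA (1 at the
#' surface to 0.8 at full depth), reflecting the denser mural-cell coverage
#' of superficial segments.
#'
#' @param config A [network_config()].
#' @return A `vd_network`: list with tibbles `nodes` (columns `id`, `kind`,
#'   `boundary_pressure`) and `segments` (columns `id`, `class`, `node_a`,
#'   `node_b`, `length`, `diameter`, `d_active_max`, `wall_thickness`,
#'   `cortical_depth`, `contractility`, `is_arteriolar`).
#' @export
#' @examples
#' net <- build_network(network_config())
#' sum(net$segments$is_arteriolar)  # 1009
build_network <- function(config = network_config()) {
  tr <- .pial_tree_edges(config$n_pa)
  ne <- length(tr$from)
  n_pial <- config$n_pial_segments
  base <- n_pial %/% ne
  if (base < 1L) {
    # fewer pial segments than tree edges: collapse to one chain per leaf
    tr <- list(from = rep(1L, config$n_pa),
               to = seq_len(config$n_pa) + 1L,
               is_leaf = rep(TRUE, config$n_pa))
    ne <- config$n_pa
    base <- n_pial %/% ne
  }
  extra <- n_pial %% ne
  chain_len <- rep(base, ne)
  if (extra > 0) chain_len[seq_len(extra)] <- base + 1L

  # path position (in segments from ABN) of each edge, for the diameter taper
  path_pos <- numeric(ne)
  for (e in seq_len(ne)) {
    pe <- match(tr$from[e], tr$to)
    path_pos[e] <- if (!is.na(pe)) path_pos[pe] + chain_len[pe] else 0
  }
  max_path <- max(path_pos + chain_len)

  n_total <- n_pial + config$n_pa * (config$segments_per_pa + nrow(config$micro))
  id <- character(n_total); cls <- character(n_total)
  na_ <- character(n_total); nb_ <- character(n_total)
  len <- numeric(n_total); dia <- numeric(n_total); dmx <- numeric(n_total)
  dep <- numeric(n_total); art <- logical(n_total)
  k <- 0L; node_ct <- 0L
  tname <- c(`1` = "ABN")
  leaf_nodes <- character(0)
  for (e in seq_len(ne)) {
    a <- tname[[as.character(tr$from[e])]]
    for (j in seq_len(chain_len[e])) {
      node_ct <- node_ct + 1L; b <- paste0("n", node_ct); k <- k + 1L
      frac <- (path_pos[e] + j) / max_path
      d <- config$pial_d_root - (config$pial_d_root - config$pial_d_leaf) * frac
      id[k] <- sprintf("P%03d", k); cls[k] <- "pial"
      na_[k] <- a; nb_[k] <- b
      len[k] <- config$pial_segment_length
      dia[k] <- d; dmx[k] <- d; dep[k] <- 0; art[k] <- TRUE
      a <- b
    }
    tname[[as.character(tr$to[e])]] <- a
    if (tr$is_leaf[e]) leaf_nodes <- c(leaf_nodes, a)
  }
  pa_total_len <- config$segments_per_pa * config$pa_segment_length
  for (p in seq_len(config$n_pa)) {
    a <- leaf_nodes[p]
    for (j in seq_len(config$segments_per_pa)) {
      node_ct <- node_ct + 1L; b <- paste0("n", node_ct); k <- k + 1L
      mid <- (j - 0.5) * config$pa_segment_length
      id[k] <- sprintf("PA%02d_%02d", p, j); cls[k] <- "PA"
      na_[k] <- a; nb_[k] <- b
      len[k] <- config$pa_segment_length
      dia[k] <- pa_taper_diameter(mid, config); dmx[k] <- dia[k]
      dep[k] <- mid; art[k] <- TRUE
      a <- b
    }
    for (m in seq_len(nrow(config$micro))) {
      node_ct <- node_ct + 1L; k <- k + 1L
      b <- if (m == nrow(config$micro)) "VBN" else paste0("n", node_ct)
      id[k] <- sprintf("M%02d_%d", p, m); cls[k] <- as.character(config$micro$class[m])
      na_[k] <- a; nb_[k] <- b
      len[k] <- config$micro$length[m]
      dia[k] <- config$micro$diameter[m]; dmx[k] <- dia[k]
      dep[k] <- pa_total_len; art[k] <- FALSE
      a <- b
    }
  }
  segments <- tibble(id = id, class = cls, node_a = na_, node_b = nb_,
                     length = len, diameter = dia, d_active_max = dmx,
                     wall_thickness = 0.1 * dmx, cortical_depth = dep,
                     contractility = ifelse(cls == "PA",
                                            1 - 0.2 * dep / pa_total_len, 1),
                     is_arteriolar = art)
  nodes <- tibble(id = unique(c("ABN", "VBN", na_, nb_)))
  nodes$kind <- ifelse(nodes$id == "ABN", "artery_boundary",
                       ifelse(nodes$id == "VBN", "vein_boundary", "interior"))
  nodes$boundary_pressure <- ifelse(nodes$id == "ABN", 60,
                                    ifelse(nodes$id == "VBN", 10, NA_real_))
  net <- structure(list(nodes = nodes, segments = segments, config = config),
                   class = "vd_network")
  validate_network(net)
  net
}

#' Validate a `vd_network`
#'
#' Checks the structural invariants: exactly one artery and one vein
#' boundary node, boundary pressures present only on boundary nodes,
#' positive lengths and diameters, wall thickness equal to 0.1 x maximal
#' active diameter, connectivity, and (when generated from a default
#' config) the PA segment count identity.
#'
#' @param net A `vd_network`.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_network <- function(net) {
  nd <- net$nodes; sg <- net$segments
  if (sum(nd$kind == "artery_boundary") != 1L ||
      sum(nd$kind == "vein_boundary") != 1L) {
    abort("A network must contain exactly one artery_boundary and one vein_boundary node.")
  }
  if (any(is.na(nd$boundary_pressure[nd$kind != "interior"])) ||
      any(!is.na(nd$boundary_pressure[nd$kind == "interior"]))) {
    abort("`boundary_pressure` must be present exactly on boundary nodes.")
  }
  if (any(sg$length <= 0) || any(sg$diameter <= 0)) {
    abort("Segment lengths and diameters must be positive.")
  }
  if (any(abs(sg$wall_thickness - 0.1 * sg$d_active_max) > 1e-9)) {
    abort("Wall thickness must equal 0.1 x d_active_max.")
  }
  miss <- setdiff(unique(c(sg$node_a, sg$node_b)), nd$id)
  if (length(miss)) abort("Segments reference unknown nodes.")
  g <- igraph::graph_from_data_frame(sg[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = nd$id)
  if (!igraph::is_connected(g)) abort("The vascular graph must be connected.")
  invisible(net)
}

#' @export
print.vd_network <- function(x, ...) {
  sg <- x$segments
  cat("<vd_network> ", nrow(x$nodes), " nodes, ", nrow(sg), " segments (",
      sum(sg$is_arteriolar), " arteriolar: ",
      sum(sg$class == "pial"), " pial + ",
      sum(sg$class == "PA"), " PA)\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.vd_network <- function(x, ...) x$segments

#' Adjacency of arteriolar segments for electrical coupling
#'
#' Two arteriolar segments are coupled iff they share a node; microvessels
#' (sphincter, transition zone, capillaries) are excluded. The result backs
#' the gap-junctional coupling loop of the macro model.
#'
#' @param net A `vd_network`.
#' @return A list with `ids` (arteriolar segment ids) and `adjacency`
#'   (symmetric sparse 0/1 Matrix).
#' @export
arteriolar_coupling <- function(net) {
  sg <- net$segments
  art <- which(sg$is_arteriolar)
  n <- length(art)
  groups <- split(rep(seq_len(n), 2L), c(sg$node_a[art], sg$node_b[art]))
  pr <- purrr::map(groups, function(ix) {
    if (length(ix) > 1L) t(utils::combn(ix, 2L)) else NULL
  })
  pr <- do.call(rbind, pr)
  adj <- if (is.null(pr)) {
    sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(n, n))
  } else {
    sparseMatrix(i = c(pr[, 1], pr[, 2]), j = c(pr[, 2], pr[, 1]),
                 x = 1, dims = c(n, n))
  }
  list(ids = sg$id[art], adjacency = adj)
}

.segment_cols <- c("id", "class", "node_a", "node_b", "length_um",
                   "diameter_um", "d_active_max_um", "h_um", "depth_um",
                   "contractility", "is_arteriolar")

#' Read and write networks
#'
#' `write_network()` serialises a network either as a CSV edge list (columns
#' `id,class,node_a,node_b,length_um,diameter_um,d_active_max_um,h_um,
#' depth_um,contractility,is_arteriolar`, with boundary pressures in a `#`
#' comment header) or as GraphML (node attributes `kind`,
#' `boundary_pressure`; edge attributes as above). `read_network()` is its
#' inverse; the round trip preserves identifiers exactly and numeric fields
#' to full double precision. The format is chosen from the file extension
#' (`.csv` or `.graphml`).
#'
#' @param net A `vd_network`.
#' @param path File path ending in `.csv` or `.graphml`.
#' @return `read_network()` returns a `vd_network`; `write_network()`
#'   returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  sg <- net$segments
  nd <- net$nodes
  if (grepl("\\.graphml$", path)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = sg$node_a, to = sg$node_b, id = sg$id,
                 node_a = sg$node_a, node_b = sg$node_b,
                 class = sg$class, length_um = sg$length,
                 diameter_um = sg$diameter, d_active_max_um = sg$d_active_max,
                 h_um = sg$wall_thickness, depth_um = sg$cortical_depth,
                 contractility = sg$contractility,
                 is_arteriolar = as.integer(sg$is_arteriolar)),
      directed = FALSE,
      vertices = data.frame(name = nd$id, kind = nd$kind,
                            boundary_pressure = ifelse(is.na(nd$boundary_pressure),
                                                       -1, nd$boundary_pressure)))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    abn <- nd$boundary_pressure[nd$kind == "artery_boundary"]
    vbn <- nd$boundary_pressure[nd$kind == "vein_boundary"]
    abn_id <- nd$id[nd$kind == "artery_boundary"]
    vbn_id <- nd$id[nd$kind == "vein_boundary"]
    hdr <- sprintf("# abn=%s abnp=%.9g vbn=%s vbnp=%.9g", abn_id, abn, vbn_id, vbn)
    df <- data.frame(id = sg$id, class = sg$class, node_a = sg$node_a,
                     node_b = sg$node_b, length_um = sg$length,
                     diameter_um = sg$diameter,
                     d_active_max_um = sg$d_active_max,
                     h_um = sg$wall_thickness, depth_um = sg$cortical_depth,
                     contractility = sg$contractility,
                     is_arteriolar = as.integer(sg$is_arteriolar))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (grepl("\\.graphml$", path)) {
    g <- igraph::read_graph(path, format = "graphml")
    va <- igraph::vertex_attr(g)
    ea <- igraph::edge_attr(g)
    need <- setdiff(c("node_a", "node_b", "class", "length_um", "diameter_um",
                      "d_active_max_um", "h_um", "depth_um", "contractility",
                      "is_arteriolar"),
                    names(ea))
    if (length(need)) {
      abort(paste0("GraphML is missing edge attributes: ",
                   paste(need, collapse = ", ")))
    }
    nodes <- tibble(id = va$name, kind = va$kind,
                    boundary_pressure = ifelse(va$boundary_pressure < 0,
                                               NA_real_, va$boundary_pressure))
    segments <- tibble(id = ea$id, class = ea$class,
                       node_a = ea$node_a, node_b = ea$node_b,
                       length = ea$length_um, diameter = ea$diameter_um,
                       d_active_max = ea$d_active_max_um,
                       wall_thickness = ea$h_um,
                       cortical_depth = ea$depth_um,
                       contractility = ea$contractility,
                       is_arteriolar = as.logical(ea$is_arteriolar))
  } else {
    hdr <- readLines(path, n = 1L)
    if (!grepl("^# abn=", hdr)) abort("CSV network is missing its boundary header line.")
    kv <- strsplit(sub("^# ", "", hdr), " ")[[1]]
    kv <- setNames(sub(".*=", "", kv), sub("=.*", "", kv))
    df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- setdiff(.segment_cols, names(df))
    if (length(need)) {
      abort(paste0("CSV network is missing columns: ", paste(need, collapse = ", ")))
    }
    segments <- tibble(id = df$id, class = df$class,
                       node_a = df$node_a, node_b = df$node_b,
                       length = df$length_um, diameter = df$diameter_um,
                       d_active_max = df$d_active_max_um,
                       wall_thickness = df$h_um,
                       cortical_depth = df$depth_um,
                       contractility = df$contractility,
                       is_arteriolar = as.logical(df$is_arteriolar))
    ids <- unique(c(segments$node_a, segments$node_b))
    nodes <- tibble(id = ids,
                    kind = ifelse(ids == kv[["abn"]], "artery_boundary",
                                  ifelse(ids == kv[["vbn"]], "vein_boundary",
                                         "interior")),
                    boundary_pressure = ifelse(ids == kv[["abn"]],
                                               as.numeric(kv[["abnp"]]),
                                               ifelse(ids == kv[["vbn"]],
                                                      as.numeric(kv[["vbnp"]]),
                                                      NA_real_)))
  }
  net <- structure(list(nodes = nodes, segments = segments, config = NULL),
                   class = "vd_network")
  validate_network(net)
  net
}
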