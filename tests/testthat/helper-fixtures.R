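# Shared fixtures, all built in code.

# chain of n equal segments from an artery terminal to a vein terminal
make_series_chain <- function(n = 2, diameter = 0.05, length = 1) {
  net <- vascular_network()
  for (i in 0:n) net <- add_network_node(net, i * length, 0, "parent")
  for (i in seq_len(n))
    net <- add_segment(net, i, i + 1L, diameter, parent = TRUE)
  list(net = net, boundary = list(artery = 1L, vein = n + 1L))
}

# symmetric Y: one inlet segment splitting into two equal branches
make_y_network <- function(diameter = 0.05) {
  net <- vascular_network()
  net <- add_network_node(net, 0, 0, "parent")
  net <- add_network_node(net, 1, 0, "junction")
  net <- add_network_node(net, 2, 0.5, "parent")
  net <- add_network_node(net, 2, -0.5, "parent")
  net <- add_segment(net, 1L, 2L, diameter)
  net <- add_segment(net, 2L, 3L, diameter)
  net <- add_segment(net, 2L, 4L, diameter)
  list(net = net, boundary = list(artery = 1L, vein = c(3L, 4L)))
}

# 4-segment toy loop: a parent vessel A - n1 - n2 (artery at A, vein at
# n2) with a free (neo) two-segment path n1 - m - n2 shunting the short
# middle parent segment.  The neo path sees only the small pressure drop
# across that short segment while the parent carries the reference flow,
# so the metabolic stimulus responds strongly to neo growth and the
# adaptation law has a stable interior fixed point.
make_toy_loop <- function(neo_d = 0.02, parent_d = 0.18) {
  net <- vascular_network()
  net <- add_network_node(net, 0, 0, "parent")      # A (artery)
  net <- add_network_node(net, 2, 0, "junction")    # n1
  net <- add_network_node(net, 2.4, 0, "parent")    # n2 (vein)
  net <- add_network_node(net, 2.2, 1, "sprout")    # m
  net <- add_segment(net, 1L, 2L, parent_d, parent = TRUE)
  net <- add_segment(net, 2L, 3L, parent_d, parent = TRUE)
  net <- add_segment(net, 2L, 4L, neo_d)
  net <- add_segment(net, 4L, 3L, neo_d)
  list(net = net, boundary = list(artery = 1L, vein = 3L))
}

# connected random network with ~n_seg segments (spanning tree + extra
# chords), random diameters, artery/vein at the two most distant nodes
make_random_network <- function(seed, n_seg = 50) {
  set.seed(seed)
  n_nodes <- ceiling(n_seg * 0.8)
  xy <- matrix(runif(2 * n_nodes, 0, 5), ncol = 2)
  net <- vascular_network()
  for (i in seq_len(n_nodes))
    net <- add_network_node(net, xy[i, 1], xy[i, 2], "sprout")
  # nearest-neighbour spanning tree
  in_tree <- 1L
  out <- setdiff(seq_len(n_nodes), in_tree)
  edges <- NULL
  while (length(out) > 0) {
    d <- outer(in_tree, out, function(a, b)
      (xy[a, 1] - xy[b, 1])^2 + (xy[a, 2] - xy[b, 2])^2)
    k <- arrayInd(which.min(d), dim(d))
    edges <- rbind(edges, c(in_tree[k[1]], out[k[2]]))
    in_tree <- c(in_tree, out[k[2]])
    out <- out[-k[2]]
  }
  extra <- n_seg - nrow(edges)
  for (e in seq_len(max(0, extra))) {
    repeat {
      ij <- sample(n_nodes, 2)
      if (!any(edges[, 1] == ij[1] & edges[, 2] == ij[2]) &&
          !any(edges[, 1] == ij[2] & edges[, 2] == ij[1])) break
    }
    edges <- rbind(edges, ij)
  }
  for (e in seq_len(nrow(edges)))
    net <- add_segment(net, edges[e, 1], edges[e, 2],
                       runif(1, 0.01, 0.1))
  d2 <- as.matrix(dist(xy))
  far <- arrayInd(which.max(d2), dim(d2))
  list(net = net, boundary = list(artery = far[1], vein = far[2]))
}

# unit-square nodal domain with its background integration mesh
unit_domain <- function(spacing = 0.1, gauss_order = 2L) {
  build_integration_mesh(discretize_domain(c(0, 1, 0, 1), spacing),
                         gauss_order = gauss_order)
}

# strip diffusion problem: D = 1, R = 1, zero concentration on the x = 0
# and x = 1 edges; closed form phi(x) = x (1 - x) / 2, max 0.125
strip_problem <- function(domain) {
  bc <- which(domain$nodes[, 1] < 1e-12 | domain$nodes[, 1] > 1 - 1e-12)
  diffusion_problem(diff_x = 1, diff_y = 1, release_rate = 1,
                    source_region = function(x, y) rep(TRUE, length(x)),
                    essential_bcs = list(nodes = bc,
                                         values = rep(0, length(bc))))
}

strip_error <- function(spacing) {
  dom <- unit_domain(spacing)
  fld <- solve_vegf(assemble_system(strip_problem(dom), dom))
  exact <- dom$nodes[, 1] * (1 - dom$nodes[, 1]) / 2
  max(abs(fld$nodal_values - exact))
}

# deterministic hash of a data frame (edge tables, fraction maps)
df_hash <- function(df) {
  paste(utils::capture.output(utils::write.csv(df, stdout())),
        collapse = "\n")
}
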