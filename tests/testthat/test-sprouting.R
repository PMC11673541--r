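test_that("migration direction rotates the normalised gradient", {
  expect_equal(migration_direction(c(1, 0), 0), c(1, 0))
  expect_equal(migration_direction(c(1, 0), pi / 2), c(0, 1),
               tolerance = 1e-12)
  expect_equal(migration_direction(c(2, 0), -pi / 2), c(0, -1),
               tolerance = 1e-12)
  set.seed(1)
  for (k in 1:20) {
    g <- rnorm(2); th <- runif(1, -pi, pi)
    expect_equal(sum(migration_direction(g, th)^2), 1, tolerance = 1e-12)
  }
  # zero gradient: previous direction, or nothing to fall back on
  expect_equal(migration_direction(c(0, 0), 0.3, fallback = c(0, 1)),
               migration_direction(c(0, 1), 0.3))
  expect_null(migration_direction(c(0, 0), 0.3))
})

test_that("inter-branch distance follows the calibrated exponential law", {
  p <- sprouting_params()
  expect_equal(branch_distance(1, p), 0.9286 * exp(-0.219), tolerance = 1e-12)
  expect_equal(branch_distance(1, p), 0.7460, tolerance = 1e-4)
  expect_equal(branch_distance(2, p), 0.5993, tolerance = 1e-4)
  expect_true(all(diff(branch_distance(1:5, p)) < 0))
})

test_that("branch-angle sampler stays in the measured ranges and recovers the means", {
  p <- sprouting_params()
  set.seed(42)
  same <- sample_branch_angle(400, "same", p)
  cross <- sample_branch_angle(400, "cross", p)
  expect_true(all(same >= 45 & same <= 127))
  expect_true(all(cross >= 44 & cross <= 117))
  expect_lt(abs(mean(same) - 68), 2)
  expect_lt(abs(mean(cross) - 86), 2)
})

test_that("a tip step lays down exactly one segment of the right length", {
  net <- vascular_network()
  net <- add_network_node(net, 1, 1, "parent")
  p <- sprouting_params()
  tip <- tip_cell(c(1, 1), attached_node = 1L)
  st <- step_tip(tip, c(0, -1), net, p, c(0, 5, 0, 5))
  expect_equal(st$event, "step")
  expect_equal(nrow(st$net$segments), 1L)
  expect_equal(st$tip$position, c(1, 1 - p$step_default))
  expect_equal(st$net$segments$length[1], p$step_default)
  expect_equal(st$tip$dist_since_branch, p$step_default)
  # second step reuses the inter-position distance as the step length
  st2 <- step_tip(st$tip, c(0, -1), st$net, p, c(0, 5, 0, 5))
  expect_equal(nrow(st2$net$segments), 2L)
  expect_equal(st2$net$segments$length[2], p$step_default)
})

test_that("a step near an existing node adopts it instead of duplicating", {
  net <- vascular_network()
  net <- add_network_node(net, 1, 1, "parent")
  net <- add_network_node(net, 1, 0.96, "sprout")  # within snap tol of target
  p <- sprouting_params()
  tip <- tip_cell(c(1, 1), attached_node = 1L)
  st <- step_tip(tip, c(0, -1), net, p, c(0, 5, 0, 5))
  expect_equal(st$event, "snap")
  expect_equal(nrow(st$net$nodes), 2L)          # no new node
  expect_equal(st$tip$attached_node, 2L)
  expect_equal(nrow(st$net$segments), 1L)
})

test_that("a tip stepping out of the domain is deactivated", {
  net <- vascular_network()
  net <- add_network_node(net, 0.01, 0.01, "parent")
  tip <- tip_cell(c(0.01, 0.01), attached_node = 1L)
  st <- step_tip(tip, c(0, -1), net, sprouting_params(), c(0, 5, 0, 5))
  expect_equal(st$event, "exit")
  expect_false(st$tip$active)
  expect_equal(nrow(st$net$segments), 0L)
})

test_that("branching needs the odometer to strictly exceed the branch distance", {
  p <- sprouting_params()
  net <- vascular_network()
  net <- add_network_node(net, 1, 1, "sprout")
  tip <- tip_cell(c(1, 1), order = 2L, attached_node = 1L,
                  direction = c(0, -1))
  tip$dist_since_branch <- branch_distance(2, p)   # exactly d: no branch
  expect_null(maybe_branch(tip, net, p)$daughter)
  tip$dist_since_branch <- branch_distance(2, p) + 1e-9
  set.seed(5)
  br <- maybe_branch(tip, net, p)
  expect_s3_class(br$daughter, "tip_cell")
  expect_equal(br$daughter$order, 3L)      # daughter increments
  expect_equal(br$tip$order, 2L)           # parent keeps its order
  expect_equal(br$tip$dist_since_branch, 0)
  expect_equal(br$type, "cross")
  expect_true(br$angle_deg >= 44 && br$angle_deg <= 117)
})

test_that("order is capped at max_order and then same-order angles apply", {
  p <- sprouting_params()
  net <- vascular_network()
  net <- add_network_node(net, 1, 1, "sprout")
  tip <- tip_cell(c(1, 1), order = 3L, attached_node = 1L,
                  direction = c(0, -1))
  tip$dist_since_branch <- 1
  set.seed(6)
  br <- maybe_branch(tip, net, p)
  expect_equal(br$daughter$order, 3L)
  expect_equal(br$type, "same")
})

test_that("cross-order branch angles over many seeded events respect the measured range", {
  p <- sprouting_params()
  net <- vascular_network()
  net <- add_network_node(net, 1, 1, "sprout")
  set.seed(11)
  angles <- replicate(250, {
    tip <- tip_cell(c(1, 1), order = 1L, attached_node = 1L,
                    direction = c(0, -1))
    tip$dist_since_branch <- 1
    maybe_branch(tip, net, p)$angle_deg
  })
  expect_true(all(angles >= 44 & angles <= 117))
  expect_lt(abs(mean(angles) - 86), 2)
})

test_that("two head-on tips fuse into one junction and a perfusable cycle", {
  p <- sprouting_params()
  net <- vascular_network()
  # parent chain along y = 1
  for (x in c(0, 0.5, 1)) net <- add_network_node(net, x, 1, "parent")
  net <- add_segment(net, 1L, 2L, 0.1, parent = TRUE)
  net <- add_segment(net, 2L, 3L, 0.1, parent = TRUE)
  # two sprouts hanging from nodes 1 and 3, tips ending close together
  net <- add_network_node(net, 0.2, 0.5, "sprout")   # 4
  net <- add_network_node(net, 0.28, 0.5, "sprout")  # 5
  net <- add_segment(net, 1L, 4L, 0.02)
  net <- add_segment(net, 3L, 5L, 0.02)
  t1 <- tip_cell(c(0.2, 0.5), attached_node = 4L); t1$prev_position <- c(0.1, 0.9)
  t2 <- tip_cell(c(0.28, 0.5), attached_node = 5L); t2$prev_position <- c(0.9, 0.9)
  an <- detect_anastomosis(net, list(t1, t2), radius = 0.1)
  expect_gte(an$merges, 1L)
  expect_false(an$tips[[1]]$active)
  g <- igraph::graph_from_edgelist(
    cbind(an$net$segments$from, an$net$segments$to), directed = FALSE)
  expect_gt(igraph::ecount(g) - igraph::vcount(g) +
              igraph::components(g)$no, 0)   # independent cycle exists
})

test_that("a tip ignores its own trailing segments", {
  net <- vascular_network()
  net <- add_network_node(net, 0, 0, "sprout")
  net <- add_network_node(net, 0.05, 0, "sprout")
  net <- add_network_node(net, 0.1, 0, "sprout")
  net <- add_segment(net, 1L, 2L, 0.02)
  net <- add_segment(net, 2L, 3L, 0.02)
  tip <- tip_cell(c(0.1, 0), attached_node = 3L)
  tip$recent_nodes <- c(1L, 2L, 3L)
  an <- detect_anastomosis(net, list(tip), radius = 0.06)
  expect_equal(an$merges, 0L)
  expect_true(an$tips[[1]]$active)
})

test_that("a tip crossing a foreign segment splits it at the projection", {
  net <- vascular_network()
  net <- add_network_node(net, 0, 0, "sprout")    # foreign segment a-b
  net <- add_network_node(net, 1, 0, "sprout")
  net <- add_segment(net, 1L, 2L, 0.03)
  net <- add_network_node(net, 0.5, 0.1, "sprout")  # approaching tip node
  tip <- tip_cell(c(0.5, 0.02), attached_node = 3L)
  tip$recent_nodes <- 3L
  an <- detect_anastomosis(net, list(tip), radius = 0.05)
  expect_equal(an$merges, 1L)
  expect_equal(nrow(an$net$nodes), 4L)   # junction inserted
  expect_equal(an$net$nodes$kind[4], "junction")
  expect_equal(nrow(an$net$segments), 3L)
  # split preserves total length
  expect_equal(sum(an$net$segments$length[c(1, 2)]), 1, tolerance = 1e-9)
})

test_that("a tip under pure chemotaxis runs straight at a point source", {
  dom <- build_integration_mesh(discretize_domain(c(0, 4, 0, 4), 0.2))
  src <- c(1, 1)
  # radially symmetric field: gradient points exactly at the source
  vals <- -((dom$nodes[, 1] - src[1])^2 + (dom$nodes[, 2] - src[2])^2)
  fld <- structure(list(domain = dom, nodal_values = vals),
                   class = "vegf_field")
  p <- sprouting_params(theta_max = 1e-9)
  net <- vascular_network()
  net <- add_network_node(net, 3, 3, "parent")
  tip <- tip_cell(c(3, 3), attached_node = 1L)
  for (k in 1:20) {
    g <- field_gradient(fld, tip$position)
    dir <- migration_direction(g, 0, fallback = tip$direction)
    st <- step_tip(tip, dir, net, p, c(0, 4, 0, 4))
    tip <- st$tip; net <- st$net
  }
  # every laid node sits on the line from (3,3) to the source
  v <- c(net$nodes$x - 3, net$nodes$y - 3)
  xs <- net$nodes$x; ys <- net$nodes$y
  cross <- (xs - 3) * (src[2] - 3) - (ys - 3) * (src[1] - 3)
  expect_lt(max(abs(cross)), p$step_default / 2)
  # and the tip moved toward the source
  expect_lt(sum((tip$position - src)^2), sum((c(3, 3) - src)^2))
})

test_that("the growth loop is deterministic, logs simulated hours, and respects bounds", {
  sc <- generate_cam_like_scenario(seed = 3, n_tips = 3)
  r0 <- run_angiogenesis(sc, n_steps = 0)
  expect_true(all(r0$network$segments$parent))
  r1 <- run_angiogenesis(sc, n_steps = 8)
  r2 <- run_angiogenesis(sc, n_steps = 8)
  expect_identical(df_hash(r1$network$segments), df_hash(r2$network$segments))
  expect_identical(df_hash(r1$network$nodes), df_hash(r2$network$nodes))
  expect_equal(r1$log$hours, 6.7 * seq_len(nrow(r1$log)))
  b <- sc$bounds
  expect_true(all(r1$network$nodes$x >= b[1] & r1$network$nodes$x <= b[2] &
                    r1$network$nodes$y >= b[3] & r1$network$nodes$y <= b[4]))
  expect_true(all(r1$network$segments$order >= 1 &
                    r1$network$segments$order <= sc$sprouting$max_order))
  # segment lengths always equal the node distance
  segs <- r1$network$segments; nd <- r1$network$nodes
  expect_equal(segs$length,
               sqrt((nd$x[segs$from] - nd$x[segs$to])^2 +
                      (nd$y[segs$from] - nd$y[segs$to])^2),
               tolerance = 1e-9)
})
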