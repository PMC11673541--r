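test_that("a spanning capillary gives the expected patch fraction", {
  net <- vascular_network()
  net <- add_network_node(net, 0, 0.5, "sprout")
  net <- add_network_node(net, 1, 0.5, "sprout")
  net <- add_segment(net, 1L, 2L, 0.1)
  fm <- volume_fraction_map(net, roi = c(0, 1, 0, 1), n = 1L)
  expect_equal(fm$grid[1, 1], 0.1)
  expect_equal(fm$total, 0.1)
})

test_that("empty networks and empty patches quantify to zero", {
  fm <- volume_fraction_map(vascular_network(), roi = c(0, 5, 0, 5))
  expect_equal(fm$grid, matrix(0, 5, 5))
  expect_equal(fm$total, 0)
  # a segment confined to one corner leaves the rest empty
  net <- vascular_network()
  net <- add_network_node(net, 0.1, 0.1, "sprout")
  net <- add_network_node(net, 0.6, 0.1, "sprout")
  net <- add_segment(net, 1L, 2L, 0.05)
  fm2 <- volume_fraction_map(net, roi = c(0, 5, 0, 5))
  expect_equal(sum(fm2$grid > 0), 1L)
  expect_equal(fm2$grid[1, 1], 0.5 * 0.05 / 1)
})

test_that("the total equals the mean of the patch fractions (exact decomposition)", {
  run <- run_angiogenesis(generate_cam_like_scenario(seed = 5, n_tips = 3),
                          n_steps = 10)
  fm <- volume_fraction_map(run$network, roi = c(0, 5, 0, 5))
  expect_equal(fm$total, mean(fm$grid), tolerance = 1e-9)
  expect_true(all(fm$grid >= 0 & fm$grid <= 1))
})

test_that("the fraction map rotates with a symmetric network", {
  # a cross through the ROI centre is invariant under 90-degree rotation
  net <- vascular_network()
  net <- add_network_node(net, 1, 2.5, "sprout")
  net <- add_network_node(net, 4, 2.5, "sprout")
  net <- add_network_node(net, 2.5, 1, "sprout")
  net <- add_network_node(net, 2.5, 4, "sprout")
  net <- add_segment(net, 1L, 2L, 0.08)
  net <- add_segment(net, 3L, 4L, 0.08)
  fm <- volume_fraction_map(net, roi = c(0, 5, 0, 5))
  # rotate the network by 90 degrees about the ROI centre and recompute
  rot <- net
  rot$nodes$x <- 2.5 - (net$nodes$y - 2.5)
  rot$nodes$y <- 2.5 + (net$nodes$x - 2.5)
  fm_rot <- volume_fraction_map(rot, roi = c(0, 5, 0, 5))
  expect_equal(fm_rot$total, fm$total, tolerance = 1e-12)
  expect_equal(fm_rot$grid, t(fm$grid[, 5:1]), tolerance = 1e-12)
})

test_that("discrepancy is zero for identical maps and 15% for 0.115 vs 0.1", {
  net <- vascular_network()
  net <- add_network_node(net, 0, 0.5, "sprout")
  net <- add_network_node(net, 1, 0.5, "sprout")
  net <- add_segment(net, 1L, 2L, 0.1)
  fm <- volume_fraction_map(net, roi = c(0, 1, 0, 1))
  expect_equal(fraction_discrepancy(fm, fm), 0)
  a <- fm; b <- fm
  a$total <- 0.115; b$total <- 0.1
  expect_equal(fraction_discrepancy(a, b), 15, tolerance = 1e-9)
  z <- fm; z$total <- 0
  expect_error(fraction_discrepancy(a, z), "zero")
  other <- volume_fraction_map(net, roi = c(0, 2, 0, 2))
  expect_error(fraction_discrepancy(fm, other), "ROI")
})

test_that("branch angles are measured at constructed junctions", {
  # one junction with a daughter at exactly 86 degrees from the parent
  net <- vascular_network()
  net <- add_network_node(net, 0, 0, "sprout")
  net <- add_network_node(net, 1, 0, "junction")
  th <- 86 * pi / 180
  net <- add_network_node(net, 1 + cos(th), sin(th), "sprout")
  net <- add_network_node(net, 2, 0, "sprout")
  net <- add_segment(net, 1L, 2L, 0.05, order = 1L)     # parent inflow
  net <- add_segment(net, 2L, 4L, 0.05, order = 1L)     # continuation
  net <- add_segment(net, 2L, 3L, 0.04, order = 2L)     # daughter
  st <- branch_angle_stats(net)
  expect_equal(nrow(st$cross), 1L)
  expect_equal(st$cross$angle_deg, 86, tolerance = 1e-9)
  expect_equal(st$summary$mean[st$summary$group == "cross"], 86,
               tolerance = 1e-9)
  expect_equal(st$summary$n[st$summary$group == "same"], 1L)
  # invariant under global translation
  sh <- net
  sh$nodes$x <- sh$nodes$x + 13.7
  sh$nodes$y <- sh$nodes$y - 2.2
  st2 <- branch_angle_stats(sh)
  expect_equal(st2$cross$angle_deg, st$cross$angle_deg, tolerance = 1e-9)
  # no junctions: empty stats
  expect_equal(nrow(branch_angle_stats(vascular_network())$summary), 0L)
})

test_that("grown networks expose measurable junction angles", {
  sc <- generate_cam_like_scenario(seed = 8, n_tips = 6)
  run <- run_angiogenesis(sc, n_steps = 17)
  st <- branch_angle_stats(run$network)
  all_ang <- c(st$same$angle_deg, st$cross$angle_deg)
  expect_gt(length(all_ang), 0)
  expect_true(all(is.finite(all_ang) & all_ang >= 0 & all_ang <= 180))
  # the angles the sampler drew for these branch events sit in the
  # calibrated ranges
  ev <- run$branch_events
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$angle_deg[ev$type == "cross"] >= 44 &
                    ev$angle_deg[ev$type == "cross"] <= 117))
})

test_that("stress summaries respect monotone set-point bounds", {
  fx <- make_toy_loop()
  fp <- flow_params()
  st <- solve_pressures(fx$net, fp, fx$boundary)
  ap <- adaptation_params()
  stim <- compute_stimuli(fx$net, st, ap)
  expect_true(all(stim$tau_e >= tau_e_stress(fp$p_vein) - 1e-9 &
                    stim$tau_e <= tau_e_stress(fp$p_artery) + 1e-9))
  sm <- stress_summary(fx$net, st, stim, ap)
  expect_setequal(unique(sm$quantity), c("tau_w", "tau_e", "tau_T"))
  expect_true(all(sm$min <= sm$max))
  # all-identical segments give zero-width ranges
  fx2 <- make_series_chain(3)
  st2 <- solve_pressures(fx2$net, fp, fx2$boundary)
  stim2 <- compute_stimuli(fx2$net, st2, ap)
  sm2 <- stress_summary(fx2$net, st2, stim2, ap)
  tw <- sm2[sm2$quantity == "tau_w", ]
  expect_equal(tw$min, tw$max, tolerance = 1e-9)
})

test_that("summaries are pure functions of the exported tables", {
  fx <- make_toy_loop()
  prefix <- tempfile()
  export_network(fx$net, prefix)
  back <- import_network(prefix)
  fm1 <- volume_fraction_map(fx$net, roi = c(0, 3, 0, 3))
  fm2 <- volume_fraction_map(back, roi = c(0, 3, 0, 3))
  expect_identical(fm1$grid, fm2$grid)
  expect_identical(fm1$total, fm2$total)
  st1 <- branch_angle_stats(fx$net)
  st2 <- branch_angle_stats(back)
  expect_identical(st1$summary, st2$summary)
})

test_that("fraction-map export writes the grid and a JSON total", {
  net <- vascular_network()
  net <- add_network_node(net, 0, 0.5, "sprout")
  net <- add_network_node(net, 1, 0.5, "sprout")
  net <- add_segment(net, 1L, 2L, 0.1)
  fm <- volume_fraction_map(net, roi = c(0, 1, 0, 1))
  path <- tempfile(fileext = ".tsv")
  export_fraction_map(fm, path)
  grid <- as.matrix(read.table(path, sep = "\t"))
  dimnames(grid) <- NULL
  expect_equal(grid, fm$grid)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$total, fm$total)
})
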