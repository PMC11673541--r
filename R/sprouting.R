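#' Tip-cell sprouting parameters
#'
#' Calibrated against CAM (chorioallantoic membrane) measurements: the
#' inter-branch distance law d = branch_a * exp(-branch_b * order) and the
#' branch-angle statistics (same-order mean 68 deg, range 45-127; cross-order
#' mean 86 deg, range 44-117).  The migration direction is the VEGF gradient
#' rotated by a uniform random angle theta in [-theta_max, theta_max]
#' radians.
#'
#' @param theta_max angular perturbation half-range (radians, default 0.24).
#' @param branch_a pre-exponential of the inter-branch distance law (mm).
#' @param branch_b decay rate per capillary order.
#' @param angle_same_mean,angle_same_range same-order branch-angle mean and
#'   `c(min, max)` (degrees).
#' @param angle_diff_mean,angle_diff_range cross-order equivalents (degrees).
#' @param step_default first-step length of a new sprout (mm); the node-snap
#'   tolerance is `step_default / 2`.
#' @param chemo_weight per-step weight of the (normalised) VEGF gradient
#'   when blended with the tip's previous direction.  Endothelial tip cells
#'   migrate with directional persistence: they turn toward the
#'   chemoattractant over several cell lengths rather than instantly, which
#'   lets branch daughters carry their branch angle outward before aligning
#'   with the gradient.
#' @param anastomosis_radius merge distance for sprout fusion (mm).
#' @param daughter_shrink daughter diameter factor per order increment.
#' @param d_floor minimum diameter assigned at creation (mm).
#' @param max_order deepest capillary order (order 1 = highest calibre).
#' @return an object of class `sprouting_params`.
#' @export
sprouting_params <- function(theta_max = 0.24, branch_a = 0.9286,
                             branch_b = 0.219,
                             angle_same_mean = 68,
                             angle_same_range = c(45, 127),
                             angle_diff_mean = 86,
                             angle_diff_range = c(44, 117),
                             step_default = 0.05,
                             chemo_weight = 0.1,
                             anastomosis_radius = 0.03,
                             daughter_shrink = 0.8,
                             d_floor = 0.01,
                             max_order = 3L) {
  stopifnot(theta_max > 0, theta_max < pi / 2, branch_a > 0, branch_b > 0,
            step_default > 0, chemo_weight > 0, chemo_weight <= 1,
            anastomosis_radius > 0, max_order >= 1,
            angle_same_range[1] <= angle_same_mean,
            angle_same_mean <= angle_same_range[2],
            angle_diff_range[1] <= angle_diff_mean,
            angle_diff_mean <= angle_diff_range[2])
  structure(list(theta_max = theta_max, branch_a = branch_a,
                 branch_b = branch_b,
                 angle_same_mean = angle_same_mean,
                 angle_same_range = angle_same_range,
                 angle_diff_mean = angle_diff_mean,
                 angle_diff_range = angle_diff_range,
                 step_default = step_default,
                 chemo_weight = chemo_weight,
                 anastomosis_radius = anastomosis_radius,
                 daughter_shrink = daughter_shrink, d_floor = d_floor,
                 max_order = as.integer(max_order)),
            class = "sprouting_params")
}

#' Create a tip cell
#'
#' @param position length-2 position (mm).
#' @param order capillary order of the sprout it leads.
#' @param attached_node network node id the sprout currently ends at.
#' @param diameter diameter assigned to segments this tip lays down (mm).
#' @param direction optional initial unit direction.
#' @return a list of class `tip_cell`.
#' @export
tip_cell <- function(position, order = 1L, attached_node = NA_integer_,
                     diameter = 0.02, direction = NULL) {
  structure(list(position = as.numeric(position),
                 prev_position = as.numeric(position),
                 direction = direction,
                 order = as.integer(order), dist_since_branch = 0,
                 active = TRUE, attached_node = as.integer(attached_node),
                 diameter = diameter,
                 recent_nodes = as.integer(attached_node)),
            class = "tip_cell")
}

#' Migration direction: perturbed VEGF gradient
#'
#' Normalises the VEGF gradient (which points toward the source) and rotates
#' it by theta through the 2D rotation matrix.  A zero gradient falls back to
#' `fallback` (the tip's previous direction); with no fallback the caller
#' should deactivate the tip.
#'
#' @param gradient length-2 VEGF gradient.
#' @param theta rotation angle (radians).
#' @param fallback optional unit direction used when the gradient vanishes.
#' @return unit length-2 direction, or NULL if the gradient is zero and no
#'   fallback exists.
#' @export
migration_direction <- function(gradient, theta, fallback = NULL) {
  nrm <- sqrt(sum(gradient^2))
  if (nrm < 1e-300 || !is.finite(nrm)) {
    if (is.null(fallback)) return(NULL)
    n <- fallback
  } else {
    n <- gradient / nrm
  }
  d <- .rotate2(n, theta)
  d / sqrt(sum(d^2))
}

#' Inter-branch distance for a capillary order
#'
#' d = branch_a * exp(-branch_b * order), in mm: higher orders (finer
#' capillaries) branch at shorter intervals.
#'
#' @param order capillary order (>= 1).
#' @param params a `sprouting_params`.
#' @return distance in mm.
#' @export
branch_distance <- function(order, params = sprouting_params()) {
  stopifnot(all(order >= 1))
  params$branch_a * exp(-params$branch_b * order)
}

#' Sample branch-angle magnitudes
#'
#' Truncated normal centred on the CAM-measured mean, with sigma set so the
#' nearer measured extreme sits at 3 sigma, rejection-clipped to the measured
#' range.  Used by [maybe_branch()] and directly for calibration checks.
#'
#' @param n number of draws.
#' @param type "same" (daughters share an order) or "cross" (orders differ).
#' @param params a `sprouting_params`.
#' @return numeric vector of angles in degrees, within the measured range.
#' @export
sample_branch_angle <- function(n, type = c("cross", "same"),
                                params = sprouting_params()) {
  type <- match.arg(type)
  if (type == "same") {
    m <- params$angle_same_mean; rng <- params$angle_same_range
  } else {
    m <- params$angle_diff_mean; rng <- params$angle_diff_range
  }
  sigma <- min(m - rng[1], rng[2] - m) / 3
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n - length(out), m, sigma)
    out <- c(out, draw[draw >= rng[1] & draw <= rng[2]])
  }
  out[seq_len(n)]
}

.rotate2 <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

#' Advance a tip cell by one step
#'
#' The step length is the distance between the tip's current and previous
#' positions (`step_default` on a sprout's first step).  If an existing
#' network node lies within the snap tolerance of the new position it is
#' adopted; otherwise a new node and segment are created.  A tip stepping
#' outside the domain bounds is deactivated.
#'
#' @param tip a `tip_cell`.
#' @param direction unit step direction (from [migration_direction()]).
#' @param net the `vascular_network`.
#' @param params a `sprouting_params`.
#' @param bounds domain bounds `c(xmin, xmax, ymin, ymax)`.
#' @param generation growth iteration counter stamped on new segments.
#' @return list(tip, net, event) where event is "step", "snap" or "exit".
#' @export
step_tip <- function(tip, direction, net, params, bounds,
                     generation = 0L) {
  stopifnot(inherits(tip, "tip_cell"), tip$active)
  step_len <- sqrt(sum((tip$position - tip$prev_position)^2))
  if (step_len < 1e-12) step_len <- params$step_default
  new_pos <- tip$position + direction * step_len
  if (new_pos[1] < bounds[1] || new_pos[1] > bounds[2] ||
      new_pos[2] < bounds[3] || new_pos[2] > bounds[4]) {
    tip$active <- FALSE
    return(list(tip = tip, net = net, event = "exit"))
  }
  snap_tol <- params$step_default / 2
  d2 <- (net$nodes$x - new_pos[1])^2 + (net$nodes$y - new_pos[2])^2
  d2[tip$recent_nodes] <- Inf   # never snap back onto the sprout's own tail
  j <- which.min(d2)
  event <- "step"
  if (length(j) == 1L && d2[j] <= snap_tol^2) {
    # the pre-existing node is adopted: the sprout has met another vessel
    target <- j
    new_pos <- c(net$nodes$x[j], net$nodes$y[j])
    event <- "snap"
  } else {
    net <- add_network_node(net, new_pos[1], new_pos[2], "sprout")
    target <- attr(net, "last_id")
  }
  net <- add_segment(net, tip$attached_node, target, tip$diameter,
                     tip$order, parent = FALSE, generation = generation)
  tip$prev_position <- tip$position
  tip$position <- new_pos
  tip$direction <- direction
  tip$dist_since_branch <- tip$dist_since_branch + step_len
  tip$attached_node <- target
  tip$recent_nodes <- utils::tail(c(tip$recent_nodes, target), 3L)
  list(tip = tip, net = net, event = event)
}

#' Possibly branch a tip cell
#'
#' A new branch forms when the distance grown since the last branch strictly
#' exceeds the order-dependent inter-branch distance.  The daughter takes
#' order parent + 1 (capped at `max_order`, in which case the daughters share
#' an order and the same-order angle statistics apply); the parent keeps its
#' order and its branch odometer resets.  The branch angle magnitude is drawn
#' from the calibrated distribution; the deflection side is random.
#'
#' @param tip a `tip_cell` (just stepped).
#' @param net the `vascular_network`.
#' @param params a `sprouting_params`.
#' @return list(tip, daughter (a `tip_cell` or NULL), angle_deg, type).
#' @export
maybe_branch <- function(tip, net, params) {
  stopifnot(inherits(tip, "tip_cell"))
  if (!tip$active || is.null(tip$direction) ||
      tip$dist_since_branch <= branch_distance(tip$order, params))
    return(list(tip = tip, daughter = NULL, angle_deg = NA_real_,
                type = NA_character_))
  d_order <- min(tip$order + 1L, params$max_order)
  type <- if (d_order == tip$order) "same" else "cross"
  ang <- sample_branch_angle(1L, type, params)
  side <- if (stats::runif(1) < 0.5) -1 else 1
  d_dir <- .rotate2(tip$direction, side * ang * pi / 180)
  d_diam <- max(tip$diameter * params$daughter_shrink, params$d_floor)
  daughter <- tip_cell(tip$position, order = d_order,
                       attached_node = tip$attached_node,
                       diameter = d_diam, direction = d_dir)
  daughter$recent_nodes <- tip$recent_nodes
  tip$dist_since_branch <- 0
  # the shared node becomes a junction
  net_kind <- net$nodes$kind[tip$attached_node]
  list(tip = tip, daughter = daughter, angle_deg = ang, type = type,
       junction_node = tip$attached_node)
}

# squared distance from point p to segment (a, b); returns list(d2, t, proj)
.point_seg_dist2 <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 < 1e-300) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  proj <- a + t * ab
  list(d2 = sum((p - proj)^2), t = t, proj = proj)
}

#' Detect and apply anastomoses
#'
#' A tip within the merge radius of any node or segment not on its own
#' recent path (its last two own segments are excluded) fuses there and
#' deactivates.  Hits on a segment interior split the segment at the
#' projection point, inserting a junction node.
#'
#' @param net the `vascular_network`.
#' @param tips list of `tip_cell`s.
#' @param radius merge distance (mm, > 0).
#' @param generation iteration stamp for segments created by merging.
#' @return list(net, tips, merges = number of fusion events).
#' @export
detect_anastomosis <- function(net, tips, radius, generation = 0L) {
  stopifnot(radius > 0)
  merges <- 0L
  for (i in seq_along(tips)) {
    tip <- tips[[i]]
    if (!tip$active || is.na(tip$attached_node)) next
    p <- tip$position
    own <- tip$recent_nodes
    # node hits first
    d2 <- (net$nodes$x - p[1])^2 + (net$nodes$y - p[2])^2
    d2[own] <- Inf
    j <- which.min(d2)
    if (length(j) == 1L && d2[j] <= radius^2) {
      if (j != tip$attached_node) {
        net <- add_segment(net, tip$attached_node, j, tip$diameter,
                           tip$order, parent = FALSE,
                           generation = generation)
        net$nodes$kind[j] <- "junction"
        tip$active <- FALSE
        tips[[i]] <- tip
        merges <- merges + 1L
        next
      }
    }
    # segment-interior hits; exclude segments touching the tip's recent path
    segs <- net$segments
    touch_own <- segs$from %in% own | segs$to %in% own
    best <- NULL; best_d2 <- radius^2
    for (s in which(!touch_own)) {
      a <- c(net$nodes$x[segs$from[s]], net$nodes$y[segs$from[s]])
      b <- c(net$nodes$x[segs$to[s]], net$nodes$y[segs$to[s]])
      ps <- .point_seg_dist2(p, a, b)
      if (ps$d2 <= best_d2) { best <- c(s, ps$t); best_d2 <- ps$d2 }
    }
    if (!is.null(best)) {
      s <- best[1]; t <- best[2]
      a_id <- segs$from[s]; b_id <- segs$to[s]
      if (t < 1e-9 || t > 1 - 1e-9) {
        hit <- if (t < 0.5) a_id else b_id
      } else {
        a <- c(net$nodes$x[a_id], net$nodes$y[a_id])
        b <- c(net$nodes$x[b_id], net$nodes$y[b_id])
        proj <- a + t * (b - a)
        net <- add_network_node(net, proj[1], proj[2], "junction")
        hit <- attr(net, "last_id")
        old <- net$segments[s, ]
        # split: replace with (a, hit) and append (hit, b)
        net$segments$to[s] <- hit
        net$segments$length[s] <- sqrt(sum((proj - a)^2))
        net <- add_segment(net, hit, b_id, old$diameter, old$order,
                           parent = old$parent, generation = old$generation)
      }
      if (hit != tip$attached_node && !(hit %in% own)) {
        net <- add_segment(net, tip$attached_node, hit, tip$diameter,
                           tip$order, parent = FALSE,
                           generation = generation)
        net$nodes$kind[hit] <- "junction"
        tip$active <- FALSE
        tips[[i]] <- tip
        merges <- merges + 1L
      }
    }
  }
  list(net = net, tips = tips, merges = merges)
}

# Add network-node coordinates to the RPIM nodal cloud, skipping any that
# nearly coincide with an existing node (coincident nodes make the radial
# moment matrix singular).
.augment_domain <- function(base, coords, tol = NULL) {
  if (is.null(tol)) tol <- min(0.005, base$spacing / 4)
  acc_x <- base$nodes[, 1]; acc_y <- base$nodes[, 2]
  keep <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(coords))) {
    x <- coords[i, 1]; y <- coords[i, 2]
    if (min((acc_x - x)^2 + (acc_y - y)^2) > tol^2) {
      keep <- rbind(keep, c(x, y))
      acc_x <- c(acc_x, x); acc_y <- c(acc_y, y)
    }
  }
  if (nrow(keep) > 0) base <- add_domain_nodes(base, keep)
  base
}

#' Run the sprouting-angiogenesis growth loop
#'
#' Per iteration: the VEGF field is re-solved with the current sprout nodes
#' added to the nodal set, every active tip advances one endothelial-cell
#' length up the perturbed gradient, tips branch when their inter-branch
#' odometer exceeds the order-dependent distance, and anastomoses are
#' detected (branching first, then merging).  One iteration corresponds to
#' about 6.7 h of CAM development.
#'
#' @param scenario a `scenario` from [generate_cam_like_scenario()] or
#'   [read_scenario()].
#' @param n_steps number of growth iterations.
#' @param seed optional master seed overriding the scenario's.
#' @return list of class `angiogenesis_run`: `network`, `tips`, `field`
#'   (final VEGF field), `log` (per-iteration data frame with simulated
#'   hours), `branch_events` (angles and order relation).
#' @export
run_angiogenesis <- function(scenario, n_steps = 30L, seed = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  if (is.null(seed)) seed <- scenario$seed
  rng <- rng_streams(seed, c("scenario", "migration", "branching"))
  built <- build_scenario_network(scenario)
  net <- built$net
  tips <- built$tips
  base_domain <- discretize_domain(scenario$bounds, scenario$spacing)
  sp <- scenario$sprouting
  log <- data.frame(iteration = integer(), hours = numeric(),
                    active_tips = integer(), segments = integer(),
                    merges = integer())
  branch_events <- data.frame(iteration = integer(), angle_deg = numeric(),
                              type = character(), stringsAsFactors = FALSE)
  field <- NULL
  if (n_steps > 0) for (it in seq_len(n_steps)) {
    if (!any(vapply(tips, function(t) t$active, logical(1)))) break
    # sprout/tip nodes enter the nodal set for this iteration's VEGF solve
    dom <- .augment_domain(base_domain,
                           cbind(net$nodes$x, net$nodes$y))
    dom <- build_integration_mesh(dom, gauss_order = scenario$rpim$gauss_order)
    field <- solve_vegf(assemble_system(
      scenario_problem(scenario, dom), dom, scenario$rpim))
    merges <- 0L
    for (i in seq_along(tips)) {
      tip <- tips[[i]]
      if (!tip$active) next
      grad <- field_gradient(field, tip$position, scenario$rpim)
      theta <- with_stream(rng, "migration",
                           function() stats::runif(1, -sp$theta_max, sp$theta_max))
      # directional persistence: blend the gradient with the previous
      # heading before the stochastic rotation
      gn <- sqrt(sum(grad^2))
      heading <- if (!is.null(tip$direction) && gn > 0)
        sp$chemo_weight * grad / gn + (1 - sp$chemo_weight) * tip$direction
      else grad
      dir <- migration_direction(heading, theta, fallback = tip$direction)
      if (is.null(dir)) { tip$active <- FALSE; tips[[i]] <- tip; next }
      st <- step_tip(tip, dir, net, sp, scenario$bounds, generation = it)
      net <- st$net
      tip <- st$tip
      if (st$event == "snap") {
        # adopting a pre-existing node fuses the sprout there
        net$nodes$kind[tip$attached_node] <- "junction"
        tip$active <- FALSE
        merges <- merges + 1L
      }
      if (tip$active) {
        br <- with_stream(rng, "branching",
                          function() maybe_branch(tip, net, sp))
        tip <- br$tip
        if (!is.null(br$daughter)) {
          net$nodes$kind[br$junction_node] <- "junction"
          tips[[length(tips) + 1L]] <- br$daughter
          branch_events[nrow(branch_events) + 1L, ] <-
            list(it, br$angle_deg, br$type)
        }
      }
      tips[[i]] <- tip
    }
    an <- detect_anastomosis(net, tips, sp$anastomosis_radius,
                             generation = it)
    net <- an$net; tips <- an$tips; merges <- merges + an$merges
    log[nrow(log) + 1L, ] <- list(
      it, 6.7 * it, sum(vapply(tips, function(t) t$active, logical(1))),
      nrow(net$segments), merges)
  }
  structure(list(network = net, tips = tips, field = field, log = log,
                 branch_events = branch_events, scenario = scenario,
                 seed = seed),
            class = "angiogenesis_run")
}
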