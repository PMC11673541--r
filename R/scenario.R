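#' Assemble a simulation scenario
#'
#' Bundles the domain geometry, parent vessel(s), hydrogel (VEGF source)
#' region, initial tip cells and all parameter blocks under a single master
#' seed.  Coordinates are continuous mm in a lower-left-origin frame.
#'
#' @param bounds domain rectangle `c(xmin, xmax, ymin, ymax)` (mm).
#' @param spacing RPIM nodal spacing (mm).
#' @param parent_vessels list of lists, each with `coords` (polyline matrix,
#'   mm), `diameter` (mm); the first polyline vertex is the artery terminal,
#'   the last the vein terminal.
#' @param hydrogel list with `centre` (mm) and `radius` (mm): the disk over
#'   which VEGF is released.
#' @param initial_tips data.frame with columns `x`, `y`, `order`,
#'   `diameter`.
#' @param rpim,sprouting,flow,adaptation parameter blocks.
#' @param parent_node_spacing polyline discretisation step (mm).
#' @param seed master RNG seed.
#' @return an object of class `scenario`.
#' @export
scenario <- function(bounds, spacing, parent_vessels, hydrogel, initial_tips,
                     rpim = rpim_params(), sprouting = sprouting_params(),
                     flow = flow_params(), adaptation = adaptation_params(),
                     parent_node_spacing = 0.1, seed = 1L) {
  sc <- structure(list(bounds = as.numeric(bounds), spacing = spacing,
                       parent_vessels = parent_vessels, hydrogel = hydrogel,
                       initial_tips = initial_tips, rpim = rpim,
                       sprouting = sprouting, flow = flow,
                       adaptation = adaptation,
                       parent_node_spacing = parent_node_spacing,
                       seed = as.integer(seed)),
                  class = "scenario")
  validate_scenario(sc)
  sc
}

#' Validate a scenario, naming the offending field
#' @param sc a `scenario`.
#' @return the scenario, invisibly; stops with a field-named error otherwise.
#' @export
validate_scenario <- function(sc) {
  b <- sc$bounds
  fail <- function(field, why) stop("scenario validation: field '", field,
                                    "' ", why, call. = FALSE)
  if (length(b) != 4 || b[2] <= b[1] || b[4] <= b[3])
    fail("bounds", "must be c(xmin, xmax, ymin, ymax) with positive extent")
  if (!is.numeric(sc$spacing) || sc$spacing <= 0)
    fail("spacing", "must be positive")
  for (pv in sc$parent_vessels) {
    if (any(pv$coords[, 1] < b[1] | pv$coords[, 1] > b[2] |
            pv$coords[, 2] < b[3] | pv$coords[, 2] > b[4]))
      fail("parent_vessels", "polyline leaves the domain bounds")
    if (pv$diameter <= 0) fail("parent_vessels", "diameter must be positive")
  }
  if (sc$hydrogel$radius <= 0) fail("hydrogel", "radius must be positive")
  ad <- sc$adaptation
  if (ad$k_p <= 0 || ad$k_p > 2) fail("k_p", "must lie in (0, 2]")
  if (ad$k_m <= 0 || ad$k_m > 2) fail("k_m", "must lie in (0, 2]")
  if (ad$k_s <= 0 || ad$k_s > 5) fail("k_s", "must lie in (0, 5]")
  if (ad$haematocrit <= 0 || ad$haematocrit >= 1)
    fail("haematocrit", "must lie in (0, 1)")
  fl <- sc$flow
  if (fl$p_artery <= fl$p_vein)
    fail("p_artery", "must exceed p_vein")
  invisible(sc)
}

#' Generate a synthetic CAM-like scenario
#'
#' Emulates the quantified CAM region of interest: a 5 x 5 mm domain, the
#' hydrogel (VEGF source) disk centred on the lower-left corner, a parent
#' vessel spanning the opposite edge with diameter drawn uniformly in
#' [0.17, 0.2] mm (artery terminal at the left end, vein at the right), and
#' 3-6 initial tip cells on the parent vessel.  All draws come from the
#' "scenario" substream of the master seed.
#'
#' @param seed master seed.
#' @param spacing RPIM nodal spacing (mm, default 0.2).
#' @param hydrogel_radius radius of the VEGF source disk (mm, default 1.5:
#'   the part of the hydrogel falling inside the ROI corner).
#' @param n_tips optional fixed tip count (default: drawn in 3..6).
#' @return a `scenario`.
#' @export
generate_cam_like_scenario <- function(seed = 1L, spacing = 0.2,
                                       hydrogel_radius = 1.5,
                                       n_tips = NULL) {
  rng <- rng_streams(seed, "scenario")
  drawn <- with_stream(rng, "scenario", function() {
    d <- stats::runif(1, 0.17, 0.2)
    k <- if (is.null(n_tips)) sample(3:6, 1) else as.integer(n_tips)
    xs <- sort(stats::runif(k, 0.75, 4.25))
    list(d = d, xs = xs)
  })
  pv <- list(list(coords = rbind(c(0, 5), c(5, 5)), diameter = drawn$d))
  tips <- data.frame(x = drawn$xs, y = 5, order = 1L, diameter = 0.02)
  scenario(bounds = c(0, 5, 0, 5), spacing = spacing,
           parent_vessels = pv,
           hydrogel = list(centre = c(0, 0), radius = hydrogel_radius),
           initial_tips = tips, seed = seed)
}

#' Build the initial vascular network and tip cells of a scenario
#'
#' Discretises each parent polyline into nodes at `parent_node_spacing`,
#' tags the first node of the first polyline as the artery terminal and the
#' last as the vein terminal, and attaches each initial tip to its nearest
#' parent node.
#'
#' @param sc a `scenario`.
#' @return list with `net`, `tips`, `boundary` (list `artery`, `vein` of
#'   node ids).
#' @export
build_scenario_network <- function(sc) {
  net <- vascular_network()
  artery <- integer(); vein <- integer()
  for (pv in sc$parent_vessels) {
    first_id <- NA_integer_; prev_id <- NA_integer_
    nseg <- nrow(pv$coords) - 1L
    for (s in seq_len(nseg)) {
      a <- pv$coords[s, ]; b <- pv$coords[s + 1L, ]
      len <- sqrt(sum((b - a)^2))
      npts <- max(2L, ceiling(len / sc$parent_node_spacing) + 1L)
      ts <- seq(0, 1, length.out = npts)
      start <- if (s == 1L) 1L else 2L
      for (q in seq(start, npts)) {
        p <- a + ts[q] * (b - a)
        net <- add_network_node(net, p[1], p[2], "parent")
        id <- attr(net, "last_id")
        if (is.na(first_id)) first_id <- id
        if (!is.na(prev_id))
          net <- add_segment(net, prev_id, id, pv$diameter, order = 1L,
                             parent = TRUE)
        prev_id <- id
      }
    }
    artery <- c(artery, first_id)
    vein <- c(vein, prev_id)
  }
  tips <- list()
  for (i in seq_len(nrow(sc$initial_tips))) {
    tp <- sc$initial_tips[i, ]
    d2 <- (net$nodes$x - tp$x)^2 + (net$nodes$y - tp$y)^2
    j <- which.min(d2)
    tips[[i]] <- tip_cell(c(net$nodes$x[j], net$nodes$y[j]),
                          order = tp$order, attached_node = j,
                          diameter = tp$diameter)
  }
  list(net = net, tips = tips, boundary = list(artery = artery, vein = vein))
}

#' Diffusion problem of a scenario on a given nodal domain
#'
#' VEGF is released over the hydrogel disk; the edge carrying the parent
#' vessel (the top edge) acts as a zero-concentration sink, so the gradient
#' points from the parent vessel toward the source.
#'
#' @param sc a `scenario`.
#' @param dom a `nodal_domain` (possibly augmented with sprout nodes).
#' @return a `diffusion_problem`.
#' @export
scenario_problem <- function(sc, dom) {
  hg <- sc$hydrogel
  src <- function(x, y) (x - hg$centre[1])^2 + (y - hg$centre[2])^2 <=
    hg$radius^2
  top <- which(abs(dom$nodes[, 2] - sc$bounds[4]) < 1e-9)
  diffusion_problem(diff_x = 1.16e-6, diff_y = 1.16e-6,
                    release_rate = 500e-6, source_region = src,
                    essential_bcs = list(nodes = top,
                                         values = rep(0, length(top))))
}

.params_to_list <- function(p) lapply(unclass(p), function(x) x)

#' Write a scenario to a structured-text (YAML) config file
#' @param sc a `scenario`.
#' @param path output path.
#' @export
write_scenario <- function(sc, path) {
  obj <- list(
    bounds = sc$bounds, spacing = sc$spacing,
    parent_vessels = lapply(sc$parent_vessels, function(pv)
      list(coords = lapply(seq_len(nrow(pv$coords)),
                           function(i) as.numeric(pv$coords[i, ])),
           diameter = pv$diameter)),
    hydrogel = list(centre = as.numeric(sc$hydrogel$centre),
                    radius = sc$hydrogel$radius),
    initial_tips = lapply(seq_len(nrow(sc$initial_tips)), function(i)
      as.list(sc$initial_tips[i, ])),
    rpim = .params_to_list(sc$rpim),
    sprouting = .params_to_list(sc$sprouting),
    flow = .params_to_list(sc$flow),
    adaptation = .params_to_list(sc$adaptation),
    parent_node_spacing = sc$parent_node_spacing,
    seed = sc$seed)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read a scenario from a YAML config file
#'
#' Missing parameter blocks fall back to their defaults; out-of-range values
#' raise a validation error naming the field.
#'
#' @param path config path.
#' @return a `scenario`.
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  need <- c("bounds", "spacing", "parent_vessels", "hydrogel",
            "initial_tips")
  for (f in need) if (is.null(obj[[f]]))
    stop("scenario config is missing required field '", f, "'")
  fill <- function(block, ctor) {
    if (is.null(block)) return(ctor())
    do.call(ctor, block[names(block) %in% names(formals(ctor))])
  }
  tips <- do.call(rbind, lapply(obj$initial_tips, as.data.frame))
  scenario(
    bounds = as.numeric(obj$bounds), spacing = obj$spacing,
    parent_vessels = lapply(obj$parent_vessels, function(pv)
      list(coords = do.call(rbind, pv$coords), diameter = pv$diameter)),
    hydrogel = list(centre = as.numeric(obj$hydrogel$centre),
                    radius = obj$hydrogel$radius),
    initial_tips = tips,
    rpim = fill(obj$rpim, rpim_params),
    sprouting = fill(obj$sprouting, sprouting_params),
    flow = fill(obj$flow, flow_params),
    adaptation = fill(obj$adaptation, adaptation_params),
    parent_node_spacing = if (is.null(obj$parent_node_spacing)) 0.1
      else obj$parent_node_spacing,
    seed = if (is.null(obj$seed)) 1L else obj$seed)
}
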