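# unit constants: internal system is mm, s, mmHg
MMHG_TO_PA <- 133.322
MMHG_TO_DYN_CM2 <- 1333.22

#' Flow-solver parameters
#'
#' @param viscosity blood viscosity (mPa s; assumed constant).
#' @param p_artery,p_vein imposed terminal pressures (mmHg); the 45/22 mmHg
#'   defaults span the reported arteriolar-to-venular range.
#' @param sor_omega SOR relaxation factor, in (0, 2).
#' @param sor_tol relative residual tolerance.
#' @param sor_maxiter sweep limit.
#' @return an object of class `flow_params`.
#' @export
flow_params <- function(viscosity = 3.5, p_artery = 45, p_vein = 22,
                        sor_omega = 1.5, sor_tol = 1e-12,
                        sor_maxiter = 50000L) {
  stopifnot(viscosity > 0, p_artery > p_vein, sor_omega > 0, sor_omega < 2,
            sor_tol > 0, sor_maxiter >= 1)
  structure(list(viscosity = viscosity, p_artery = p_artery,
                 p_vein = p_vein, sor_omega = sor_omega, sor_tol = sor_tol,
                 sor_maxiter = as.integer(sor_maxiter)),
            class = "flow_params")
}

#' Poiseuille conductance of a cylindrical segment
#'
#' g = pi D^4 / (128 mu L).  With `units = "physiological"` (the default)
#' diameters and lengths are mm, viscosity mPa s, and the conductance is
#' scaled so that pressures in mmHg yield flows in mm^3 s^-1.  With
#' `units = "consistent"` no conversion is applied.
#'
#' @param diameter,length segment geometry (> 0).
#' @param viscosity dynamic viscosity.
#' @param units "physiological" or "consistent".
#' @return conductance (mm^3 s^-1 mmHg^-1 for physiological units).
#' @export
segment_conductance <- function(diameter, length, viscosity,
                                units = c("physiological", "consistent")) {
  units <- match.arg(units)
  if (any(diameter <= 0) || any(length <= 0) || viscosity <= 0)
    stop("segment geometry and viscosity must be positive")
  g <- pi * diameter^4 / (128 * viscosity * length)
  if (units == "physiological") g <- g * MMHG_TO_PA * 1e3
  g
}

#' Wall shear stress of a segment
#'
#' tau_w = 32 mu |Q| / (pi D^3), reported in dyn cm^-2 for mm/s/mPa s
#' inputs.
#'
#' @param flow signed volumetric flow (mm^3 s^-1).
#' @param diameter segment diameter (mm, > 0).
#' @param viscosity blood viscosity (mPa s).
#' @return wall shear stress (dyn cm^-2).
#' @export
wall_shear <- function(flow, diameter, viscosity) {
  if (any(diameter <= 0)) stop("diameter must be positive")
  32 * viscosity * abs(flow) * 0.01 / (pi * diameter^3)
}

#' Solve nodal pressures and segment flows on a capillary graph
#'
#' Imposes the artery/vein terminal pressures, then relaxes the nodal
#' conservation system (zero net volumetric flow at every interior node,
#' with Poiseuille conductances) by successive over-relaxation until the
#' relative residual drops below `sor_tol`.  Dead-end sprout tips are
#' natural zero-flow boundaries.  Blood is confined to the lumen: the only
#' pressure conditions are those at the tagged terminals.
#'
#' @param net a `vascular_network`.
#' @param params a `flow_params`.
#' @param boundary list with `artery` and `vein` node-id vectors.
#' @param warm_start optional pressure vector used as the initial iterate.
#' @return an object of class `flow_state`: `pressures` (mmHg, per node),
#'   `flows` (mm^3 s^-1, per segment, signed from -> to), `conductances`,
#'   `wall_shear` (dyn cm^-2), `iterations_used`.
#' @export
solve_pressures <- function(net, params = flow_params(), boundary,
                            warm_start = NULL) {
  stopifnot(inherits(net, "vascular_network"))
  nn <- nrow(net$nodes)
  segs <- net$segments
  if (nrow(segs) == 0L) stop("network has no segments")
  bc_nodes <- c(boundary$artery, boundary$vein)
  bc_vals <- c(rep(params$p_artery, length(boundary$artery)),
               rep(params$p_vein, length(boundary$vein)))
  if (length(bc_nodes) == 0L)
    stop("no pressure-boundary nodes: tag parent terminals as artery/vein")
  # every connected component must be anchored by a boundary node
  g <- igraph::graph_from_edgelist(cbind(segs$from, segs$to), directed = FALSE)
  if (igraph::vcount(g) < nn) g <- igraph::add_vertices(g, nn - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  used <- sort(unique(comp[c(segs$from, segs$to)]))
  if (!all(used %in% comp[bc_nodes]))
    stop("isolated network component without a pressure boundary node; ",
         "the pressure system is singular")
  cond <- segment_conductance(segs$diameter, segs$length, params$viscosity)
  # adjacency lists
  adj_n <- vector("list", nn); adj_g <- vector("list", nn)
  for (s in seq_len(nrow(segs))) {
    a <- segs$from[s]; b <- segs$to[s]
    adj_n[[a]] <- c(adj_n[[a]], b); adj_g[[a]] <- c(adj_g[[a]], cond[s])
    adj_n[[b]] <- c(adj_n[[b]], a); adj_g[[b]] <- c(adj_g[[b]], cond[s])
  }
  p <- if (is.null(warm_start)) rep((params$p_artery + params$p_vein) / 2, nn)
       else as.numeric(warm_start)
  p[bc_nodes] <- bc_vals
  free <- setdiff(which(!vapply(adj_n, is.null, logical(1))), bc_nodes)
  gsum <- vapply(seq_len(nn), function(i)
    if (is.null(adj_g[[i]])) 0 else sum(adj_g[[i]]), numeric(1))
  scale <- params$p_artery - params$p_vein
  omega <- params$sor_omega
  it <- 0L
  repeat {
    it <- it + 1L
    res <- 0
    for (i in free) {
      pbar <- sum(adj_g[[i]] * p[adj_n[[i]]]) / gsum[i]
      # per-node pressure residual: robust across the wide conductance
      # range of mixed parent/capillary networks
      res <- max(res, abs(pbar - p[i]))
      p[i] <- (1 - omega) * p[i] + omega * pbar
    }
    if (res / scale < params$sor_tol) break
    if (it >= params$sor_maxiter)
      stop("SOR failed to converge in ", params$sor_maxiter,
           " sweeps (relative residual ", signif(res / scale, 3), ")")
  }
  flows <- cond * (p[segs$from] - p[segs$to])
  structure(list(pressures = p, flows = flows, conductances = cond,
                 wall_shear = wall_shear(flows, segs$diameter,
                                         params$viscosity),
                 iterations_used = it, boundary = boundary,
                 params = params),
            class = "flow_state")
}

#' Direct (sparse Cholesky) solve of the nodal pressure system
#'
#' Independent reference solution for the same weighted-Laplacian system
#' that [solve_pressures()] relaxes iteratively.
#'
#' @inheritParams solve_pressures
#' @return pressure vector (mmHg, per node).
#' @export
solve_pressures_direct <- function(net, params = flow_params(), boundary) {
  nn <- nrow(net$nodes)
  segs <- net$segments
  cond <- segment_conductance(segs$diameter, segs$length, params$viscosity)
  L <- Matrix::sparseMatrix(
    i = c(segs$from, segs$to, segs$from, segs$to),
    j = c(segs$to, segs$from, segs$from, segs$to),
    x = c(-cond, -cond, cond, cond), dims = c(nn, nn))
  bc_nodes <- c(boundary$artery, boundary$vein)
  bc_vals <- c(rep(params$p_artery, length(boundary$artery)),
               rep(params$p_vein, length(boundary$vein)))
  connected <- which(tabulate(c(segs$from, segs$to), nn) > 0)
  free <- setdiff(connected, bc_nodes)
  p <- rep(NA_real_, nn)
  p[bc_nodes] <- bc_vals
  rhs <- -as.numeric(L[free, bc_nodes, drop = FALSE] %*% bc_vals)
  p[free] <- as.numeric(Matrix::solve(L[free, free, drop = FALSE], rhs))
  p[is.na(p)] <- (params$p_artery + params$p_vein) / 2
  p
}

#' Maximum interior nodal flow imbalance
#'
#' Conservation check: the largest absolute net volumetric flow over
#' non-boundary nodes, optionally relative to the largest segment flow.
#'
#' @param net a `vascular_network`.
#' @param state a `flow_state`.
#' @param relative divide by max |segment flow|.
#' @return scalar imbalance (mm^3 s^-1, or dimensionless if relative).
#' @export
check_conservation <- function(net, state, relative = TRUE) {
  nn <- nrow(net$nodes)
  segs <- net$segments
  nf <- numeric(nn)
  for (s in seq_len(nrow(segs))) {
    nf[segs$from[s]] <- nf[segs$from[s]] - state$flows[s]
    nf[segs$to[s]] <- nf[segs$to[s]] + state$flows[s]
  }
  bc <- c(state$boundary$artery, state$boundary$vein)
  interior <- setdiff(which(tabulate(c(segs$from, segs$to), nn) > 0), bc)
  imb <- if (length(interior) == 0) 0 else max(abs(nf[interior]))
  if (relative) {
    qm <- max(abs(state$flows))
    if (qm > 0) imb <- imb / qm
  }
  imb
}

#' Join a flow state onto the network's export tables
#'
#' Writes `<prefix>_segments.csv` with flow_mm3_s, pressure_drop_mmHg and
#' wall_shear_dyn_cm2 columns appended and `<prefix>_nodes.csv` with
#' pressure_mmHg.
#'
#' @param net a `vascular_network`.
#' @param state a `flow_state`.
#' @param prefix output path prefix.
#' @export
export_flow <- function(net, state, prefix) {
  nodes <- cbind(net$nodes, pressure_mmHg = state$pressures)
  segs <- data.frame(id = net$segments$id, node_a = net$segments$from,
                     node_b = net$segments$to,
                     diameter_mm = net$segments$diameter,
                     order = net$segments$order,
                     parent = net$segments$parent,
                     length_mm = net$segments$length,
                     flow_mm3_s = state$flows,
                     pressure_drop_mmHg =
                       state$pressures[net$segments$from] -
                       state$pressures[net$segments$to],
                     wall_shear_dyn_cm2 = state$wall_shear)
  utils::write.csv(nodes, paste0(prefix, "_nodes.csv"), row.names = FALSE)
  utils::write.csv(segs, paste0(prefix, "_segments.csv"), row.names = FALSE)
  invisible(prefix)
}
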