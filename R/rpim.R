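#' RPIM discretisation parameters
#'
#' Shape parameters of the multiquadric radial basis
#' r_i(x) = ((x_i-x)^2 + (y_i-y)^2 + c^2)^p, the influence-domain size and
#' the Gauss-Legendre order of the background integration cells.  The
#' defaults c = 0.0001 and p = 0.9999 are the optimised values for this
#' nearly-linear multiquadric; c is an absolute length in mm.
#'
#' @param c multiquadric shape parameter (> 0, mm).
#' @param p_exp multiquadric exponent, in (0, 2).
#' @param n_influence nodes per influence domain (>= 4).
#' @param gauss_order quadrature order per cell axis (>= 1).
#' @return an object of class `rpim_params`.
#' @export
rpim_params <- function(c = 1e-4, p_exp = 0.9999, n_influence = 16L,
                        gauss_order = 2L) {
  stopifnot(c > 0, p_exp > 0, p_exp < 2, n_influence >= 4, gauss_order >= 1)
  structure(list(c = c, p_exp = p_exp,
                 n_influence = as.integer(n_influence),
                 gauss_order = as.integer(gauss_order)),
            class = "rpim_params")
}

#' Discretise a rectangular domain with a regular node lattice
#'
#' @param bounds numeric length-4 vector `c(xmin, xmax, ymin, ymax)` in mm.
#' @param spacing nodal spacing in mm (> 0; at least 3 nodes per axis).
#' @return an object of class `nodal_domain` with fields `nodes` (matrix,
#'   one row per node), `bounds`, `spacing`, and (after
#'   [build_integration_mesh()]) `ip`, `ip_w`, `cell_grid`.
#' @export
discretize_domain <- function(bounds, spacing) {
  bounds <- as.numeric(bounds)
  if (length(bounds) != 4L || bounds[2] <= bounds[1] || bounds[4] <= bounds[3])
    stop("invalid domain: bounds must be c(xmin, xmax, ymin, ymax) with positive extent")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("invalid domain: spacing must be a positive scalar")
  nx <- round((bounds[2] - bounds[1]) / spacing) + 1L
  ny <- round((bounds[4] - bounds[3]) / spacing) + 1L
  if (nx < 3L || ny < 3L)
    stop("invalid domain: need at least 3 nodes per axis")
  xs <- seq(bounds[1], bounds[2], length.out = nx)
  ys <- seq(bounds[3], bounds[4], length.out = ny)
  nodes <- cbind(x = rep(xs, times = ny), y = rep(ys, each = nx))
  structure(list(nodes = nodes, bounds = bounds, spacing = spacing,
                 n_lattice = c(nx, ny), ip = NULL, ip_w = NULL,
                 cell_grid = NULL),
            class = "nodal_domain")
}

#' Append nodes to an existing nodal domain
#'
#' Used as sprouts grow: tip-cell and sprout nodes enter the nodal set so the
#' VEGF field resolves around the advancing front.  Points outside the domain
#' bounds are rejected.
#'
#' @param domain a `nodal_domain`.
#' @param coords matrix (or length-2 vector) of new node positions in mm.
#' @return the domain with nodes appended.
#' @export
add_domain_nodes <- function(domain, coords) {
  stopifnot(inherits(domain, "nodal_domain"))
  coords <- rbind(coords)
  b <- domain$bounds
  inside <- coords[, 1] >= b[1] & coords[, 1] <= b[2] &
    coords[, 2] >= b[3] & coords[, 2] <= b[4]
  if (!all(inside)) stop("new nodes must lie within the domain bounds")
  domain$nodes <- rbind(domain$nodes, coords)
  domain
}

#' Build the background Gauss-Legendre integration mesh
#'
#' Quadrilateral regular cells tile the domain exactly; each carries a
#' tensor-product Gauss-Legendre rule scaled by the cell Jacobian, so the
#' weights sum to the domain area to round-off.
#'
#' @param domain a `nodal_domain`.
#' @param cells integer length-2 `c(nx, ny)` cell counts (default: one cell
#'   per nodal lattice interval).
#' @param gauss_order points per cell axis.
#' @return the domain with `ip` (integration-point coordinates), `ip_w`
#'   (weights, mm^2) and `cell_grid` filled.
#' @export
build_integration_mesh <- function(domain, cells = NULL, gauss_order = 2L) {
  stopifnot(inherits(domain, "nodal_domain"), gauss_order >= 1)
  if (is.null(cells)) cells <- domain$n_lattice - 1L
  cells <- as.integer(cells)
  if (length(cells) == 1L) cells <- c(cells, cells)
  if (any(cells < 1L)) stop("need at least one integration cell per axis")
  b <- domain$bounds
  hx <- (b[2] - b[1]) / cells[1]
  hy <- (b[4] - b[3]) / cells[2]
  gl <- pracma::gaussLegendre(gauss_order, -1, 1)
  # per-cell points in reference coords, then map to each cell
  gx <- rep(gl$x, times = gauss_order)
  gy <- rep(gl$x, each = gauss_order)
  gw <- rep(gl$w, times = gauss_order) * rep(gl$w, each = gauss_order)
  cx <- b[1] + (seq_len(cells[1]) - 0.5) * hx
  cy <- b[3] + (seq_len(cells[2]) - 0.5) * hy
  centres <- cbind(rep(cx, times = cells[2]), rep(cy, each = cells[1]))
  npt <- gauss_order^2
  ip <- cbind(
    rep(centres[, 1], each = npt) + rep(gx, nrow(centres)) * hx / 2,
    rep(centres[, 2], each = npt) + rep(gy, nrow(centres)) * hy / 2
  )
  colnames(ip) <- c("x", "y")
  domain$ip <- ip
  domain$ip_w <- rep(gw, nrow(centres)) * (hx * hy / 4)
  domain$cell_grid <- cells
  domain
}

#' Influence domain of a query point
#'
#' The `n_influence` nodes nearest the query point by Euclidean distance;
#' distance ties (frequent on a regular lattice) are broken by node
#' coordinates (y, then x), which is deterministic and independent of the
#' order in which nodes were added.
#'
#' @param point length-2 numeric position (mm).
#' @param domain a `nodal_domain`.
#' @param n_influence number of nodes.
#' @return integer vector of node indices.
#' @export
influence_nodes <- function(point, domain, n_influence) {
  n <- nrow(domain$nodes)
  if (n < n_influence)
    stop("domain has fewer nodes (", n, ") than n_influence (", n_influence, ")")
  d2 <- (domain$nodes[, 1] - point[1])^2 + (domain$nodes[, 2] - point[2])^2
  order(d2, domain$nodes[, 2], domain$nodes[, 1])[seq_len(n_influence)]
}

# multiquadric values and x/y derivatives of r_i at a query point,
# given node coordinates X (n x 2)
.mq_eval <- function(point, X, c, p) {
  dx <- point[1] - X[, 1]
  dy <- point[2] - X[, 2]
  s <- dx^2 + dy^2 + c^2
  r <- s^p
  sp1 <- p * s^(p - 1)
  list(r = r, drx = sp1 * 2 * dx, dry = sp1 * 2 * dy)
}

#' Radial point interpolation shape functions at a point
#'
#' Builds the moment system over the influence domain — the multiquadric
#' radial matrix augmented with a single unity row/column enforcing constant
#' (partition-of-unity) reproduction — and solves it for the shape-function
#' values and their x/y derivatives.  The Lagrange multiplier is a by-product
#' of the solve and is not returned.
#'
#' @param point length-2 numeric position (mm).
#' @param domain a `nodal_domain`.
#' @param params an `rpim_params`.
#' @return list with `node_ids`, `values`, `dx`, `dy`.
#' @export
rpi_shape <- function(point, domain, params = rpim_params()) {
  ids <- influence_nodes(point, domain, params$n_influence)
  X <- domain$nodes[ids, , drop = FALSE]
  n <- nrow(X)
  c2 <- params$c
  p <- params$p_exp
  # radial moment matrix R[i, j] = r_j(x_i); symmetric for the multiquadric
  ddx <- outer(X[, 1], X[, 1], "-")
  ddy <- outer(X[, 2], X[, 2], "-")
  R <- (ddx^2 + ddy^2 + c2^2)^p
  G <- rbind(cbind(R, 1), c(rep(1, n), 0))
  q <- .mq_eval(point, X, c2, p)
  rhs <- cbind(c(q$r, 1), c(q$drx, 0), c(q$dry, 0))
  sol <- tryCatch(solve(G, rhs), error = function(e)
    stop("singular RPIM moment matrix at point (", point[1], ", ", point[2],
         "); adjust n_influence or shape parameters", call. = FALSE))
  list(node_ids = ids, values = sol[seq_len(n), 1],
       dx = sol[seq_len(n), 2], dy = sol[seq_len(n), 3])
}

#' Steady-state VEGF diffusion problem
#'
#' D_x d2phi/dx2 + D_y d2phi/dy2 + R = 0 with an optional Helmholtz reaction
#' term g*phi (VEGF decay) and essential (fixed-concentration) boundary
#' conditions.  The release rate R acts as a volumetric source over the
#' region where `source_region(x, y)` is TRUE (the hydrogel).
#'
#' @param diff_x,diff_y diffusion coefficients (mm^2 s^-1, > 0).
#' @param release_rate VEGF release R over the source region (g mm^-3; the
#'   source density of the balance equation).
#' @param source_region predicate `function(x, y)` returning logical.
#' @param reaction_g Helmholtz reaction coefficient (s^-1, default 0).
#' @param essential_bcs list with `nodes` (indices) and `values`.
#' @return an object of class `diffusion_problem`.
#' @export
diffusion_problem <- function(diff_x = 1.16e-6, diff_y = diff_x,
                              release_rate = 500e-6,
                              source_region = function(x, y) rep(FALSE, length(x)),
                              reaction_g = 0,
                              essential_bcs = list(nodes = integer(), values = numeric())) {
  stopifnot(diff_x > 0, diff_y > 0, release_rate >= 0, reaction_g >= 0,
            is.function(source_region))
  structure(list(diff_x = diff_x, diff_y = diff_y, release_rate = release_rate,
                 source_region = source_region, reaction_g = reaction_g,
                 essential_bcs = essential_bcs),
            class = "diffusion_problem")
}

#' Assemble the RPIM weak-form system
#'
#' K = K_D + K_g with K_D = sum_I w_I B^T D B (diffusion), K_g = sum_I w_I g
#' phi phi^T (reaction), and source vector f_q = sum_I w_I R phi over
#' integration points inside the source region.  K is symmetric for
#' isotropic D.
#'
#' @param problem a `diffusion_problem`.
#' @param domain a `nodal_domain` with integration mesh built.
#' @param params an `rpim_params`.
#' @return list of class `rpim_system` with sparse `K`, `f`, the domain and
#'   problem.
#' @export
assemble_system <- function(problem, domain, params = rpim_params()) {
  stopifnot(inherits(problem, "diffusion_problem"),
            inherits(domain, "nodal_domain"))
  if (is.null(domain$ip) || nrow(domain$ip) == 0L)
    stop("integration mesh is empty; call build_integration_mesh() first")
  nn <- nrow(domain$nodes)
  nip <- nrow(domain$ip)
  k <- params$n_influence
  in_src <- problem$source_region(domain$ip[, 1], domain$ip[, 2])
  nk <- k * k
  ti <- integer(nip * nk); tj <- integer(nip * nk); tx <- numeric(nip * nk)
  f <- numeric(nn)
  for (I in seq_len(nip)) {
    sh <- rpi_shape(domain$ip[I, ], domain, params)
    w <- domain$ip_w[I]
    kel <- w * (problem$diff_x * tcrossprod(sh$dx) +
                  problem$diff_y * tcrossprod(sh$dy))
    if (problem$reaction_g > 0)
      kel <- kel + w * problem$reaction_g * tcrossprod(sh$values)
    idx <- (I - 1L) * nk + seq_len(nk)
    ti[idx] <- rep(sh$node_ids, times = k)
    tj[idx] <- rep(sh$node_ids, each = k)
    tx[idx] <- as.vector(kel)
    if (in_src[I] && problem$release_rate > 0)
      f[sh$node_ids] <- f[sh$node_ids] + w * problem$release_rate * sh$values
  }
  K <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(nn, nn))
  structure(list(K = K, f = f, domain = domain, problem = problem,
                 params = params),
            class = "rpim_system")
}

#' Solve the assembled VEGF system under essential boundary conditions
#'
#' Essential conditions are imposed by row/column elimination, keeping the
#' reduced system symmetric; constrained nodes hold their imposed values
#' exactly.
#'
#' @param system an `rpim_system` from [assemble_system()].
#' @param essential_bcs list with `nodes` and `values`; defaults to those of
#'   the problem.
#' @return an object of class `vegf_field` with the domain and
#'   `nodal_values` (g mm^-3).
#' @export
solve_vegf <- function(system, essential_bcs = NULL) {
  stopifnot(inherits(system, "rpim_system"))
  bc <- if (is.null(essential_bcs)) system$problem$essential_bcs else essential_bcs
  if (length(bc$nodes) == 0L && system$problem$reaction_g == 0)
    stop("no essential boundary conditions: the pure-diffusion system is singular")
  nn <- nrow(system$domain$nodes)
  bc_nodes <- as.integer(bc$nodes)
  bc_values <- rep_len(as.numeric(bc$values), length(bc_nodes))
  free <- setdiff(seq_len(nn), bc_nodes)
  u <- numeric(nn)
  u[bc_nodes] <- bc_values
  rhs <- system$f[free]
  if (length(bc_nodes) > 0L)
    rhs <- rhs - as.numeric(system$K[free, bc_nodes, drop = FALSE] %*% bc_values)
  sol <- tryCatch(
    Matrix::solve(system$K[free, free, drop = FALSE], rhs),
    error = function(e)
      stop("constrained VEGF system is singular; check that the essential ",
           "boundary conditions constrain every connected part of the domain",
           call. = FALSE))
  u[free] <- as.numeric(sol)
  structure(list(domain = system$domain, nodal_values = u),
            class = "vegf_field")
}

.check_in_bounds <- function(point, bounds) {
  if (point[1] < bounds[1] || point[1] > bounds[2] ||
      point[2] < bounds[3] || point[2] > bounds[4])
    stop("point (", point[1], ", ", point[2], ") lies outside the domain bounds")
}

#' Interpolate a VEGF field at a point
#'
#' @param field a `vegf_field`.
#' @param point length-2 numeric position (mm), inside the domain bounds.
#' @param params an `rpim_params`.
#' @return interpolated concentration (g mm^-3).
#' @export
interpolate_field <- function(field, point, params = rpim_params()) {
  stopifnot(inherits(field, "vegf_field"))
  .check_in_bounds(point, field$domain$bounds)
  sh <- rpi_shape(point, field$domain, params)
  sum(sh$values * field$nodal_values[sh$node_ids])
}

#' Gradient of a VEGF field at a point
#'
#' @inheritParams interpolate_field
#' @return length-2 numeric gradient (g mm^-3 per mm).
#' @export
field_gradient <- function(field, point, params = rpim_params()) {
  stopifnot(inherits(field, "vegf_field"))
  .check_in_bounds(point, field$domain$bounds)
  sh <- rpi_shape(point, field$domain, params)
  c(sum(sh$dx * field$nodal_values[sh$node_ids]),
    sum(sh$dy * field$nodal_values[sh$node_ids]))
}

#' Export a VEGF field as a delimited grid with a JSON sidecar
#'
#' Writes `(x, y, value)` rows for every node plus `<path>.json` holding the
#' domain metadata (bounds, spacing, coordinate convention).
#'
#' @param field a `vegf_field`.
#' @param path output file path for the delimited grid.
#' @export
export_field <- function(field, path) {
  stopifnot(inherits(field, "vegf_field"))
  df <- data.frame(x = field$domain$nodes[, 1], y = field$domain$nodes[, 2],
                   value = field$nodal_values)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(bounds_mm = field$domain$bounds, spacing_mm = field$domain$spacing,
               units = "g mm^-3",
               frame = "lower-left origin, x right, y up, mm")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
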