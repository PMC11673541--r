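# length of the part of segment (a, b) inside rect c(x0, x1, y0, y1)
# (Liang-Barsky parametric clipping)
.clip_length <- function(a, b, rect) {
  d <- b - a
  t0 <- 0; t1 <- 1
  for (k in 1:2) {
    lo <- rect[2 * k - 1]; hi <- rect[2 * k]
    if (abs(d[k]) < 1e-300) {
      if (a[k] < lo || a[k] > hi) return(0)
    } else {
      ta <- (lo - a[k]) / d[k]; tb <- (hi - a[k]) / d[k]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(0)
    }
  }
  (t1 - t0) * sqrt(sum(d^2))
}

#' Patchwise capillary volume-fraction map
#'
#' Divides the region of interest into an n x n grid of square patches and
#' computes, per patch, the projected area fraction covered by capillaries:
#' sum over segments of (length clipped to the patch) x diameter, divided
#' by the patch area.  This matches 2D projected-image quantification.
#' Patch boundaries are half-open, so shared edges are never double
#' counted.
#'
#' @param net a `vascular_network` (may be empty: all-zero map).
#' @param roi rectangle `c(xmin, xmax, ymin, ymax)` (mm).
#' @param n patches per axis (default 5).
#' @return an object of class `fraction_map` with `grid` (n x n matrix,
#'   rows = y from bottom, cols = x from left), `total` (whole-ROI
#'   fraction) and `roi`.
#' @export
volume_fraction_map <- function(net, roi = c(0, 5, 0, 5), n = 5L) {
  stopifnot(inherits(net, "vascular_network"), length(roi) == 4,
            roi[2] > roi[1], roi[4] > roi[3], n >= 1)
  hx <- (roi[2] - roi[1]) / n
  hy <- (roi[4] - roi[3]) / n
  grid <- matrix(0, n, n)
  total_area <- 0
  segs <- net$segments
  for (s in seq_len(nrow(segs))) {
    a <- c(net$nodes$x[segs$from[s]], net$nodes$y[segs$from[s]])
    b <- c(net$nodes$x[segs$to[s]], net$nodes$y[segs$to[s]])
    total_area <- total_area + segs$diameter[s] * .clip_length(a, b, roi)
    # only patches overlapped by the segment's bounding box
    cl <- function(k, nmax) min(nmax, max(1L, k))
    ix <- seq(cl(floor((min(a[1], b[1]) - roi[1]) / hx) + 1L, n),
              cl(floor((max(a[1], b[1]) - roi[1]) / hx) + 1L, n))
    iy <- seq(cl(floor((min(a[2], b[2]) - roi[3]) / hy) + 1L, n),
              cl(floor((max(a[2], b[2]) - roi[3]) / hy) + 1L, n))
    for (i in ix) for (j in iy) {
      rect <- c(roi[1] + (i - 1) * hx, roi[1] + i * hx,
                roi[3] + (j - 1) * hy, roi[3] + j * hy)
      len <- .clip_length(a, b, rect)
      if (len > 0) grid[j, i] <- grid[j, i] + segs$diameter[s] * len
    }
  }
  grid <- grid / (hx * hy)
  structure(list(grid = grid, total = total_area /
                   ((roi[2] - roi[1]) * (roi[4] - roi[3])), roi = roi),
            class = "fraction_map")
}

#' Percent discrepancy between two fraction maps
#'
#' 100 |total_sim - total_ref| / total_ref, the headline comparison between
#' a simulated network and a reference quantification.
#'
#' @param sim,ref `fraction_map`s over matching ROIs.
#' @return percent discrepancy.
#' @export
fraction_discrepancy <- function(sim, ref) {
  stopifnot(inherits(sim, "fraction_map"), inherits(ref, "fraction_map"))
  if (max(abs(sim$roi - ref$roi)) > 1e-9)
    stop("fraction maps cover different ROIs")
  if (ref$total == 0)
    stop("reference map has zero total fraction: discrepancy undefined")
  100 * abs(sim$total - ref$total) / ref$total
}

#' Branch-angle statistics of a capillary graph
#'
#' At every junction (degree >= 3) the parent direction is that of the
#' earliest segment arriving at the junction; each later segment leaving it
#' is a daughter.  Angles (degrees, in [0, 180]) are grouped by whether the
#' daughter shares the parent's capillary order.
#'
#' @param net a `vascular_network`.
#' @return list with data frames `same` and `cross` (junction, angle_deg)
#'   and a `summary` data.frame (group, n, mean, min, max); empty when the
#'   network has no junctions.
#' @export
branch_angle_stats <- function(net) {
  deg <- node_degree(net)
  junctions <- which(deg >= 3)
  rows <- list()
  segs <- net$segments
  for (j in junctions) {
    incoming <- which(segs$to == j)
    outgoing <- which(segs$from == j)
    if (length(incoming) == 0 || length(outgoing) == 0) next
    pseg <- incoming[which.min(segs$id[incoming])]
    pdir <- c(net$nodes$x[j] - net$nodes$x[segs$from[pseg]],
              net$nodes$y[j] - net$nodes$y[segs$from[pseg]])
    pn <- sqrt(sum(pdir^2)); if (pn == 0) next
    pdir <- pdir / pn
    for (dseg in outgoing) {
      if (segs$id[dseg] <= segs$id[pseg]) next
      ddir <- c(net$nodes$x[segs$to[dseg]] - net$nodes$x[j],
                net$nodes$y[segs$to[dseg]] - net$nodes$y[j])
      dn <- sqrt(sum(ddir^2)); if (dn == 0) next
      ddir <- ddir / dn
      ang <- acos(pmin(pmax(sum(pdir * ddir), -1), 1)) * 180 / pi
      rows[[length(rows) + 1L]] <- data.frame(
        junction = j, angle_deg = ang,
        group = if (segs$order[dseg] == segs$order[pseg]) "same" else "cross",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(list(same = data.frame(), cross = data.frame(),
                summary = data.frame()))
  all <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(all, all$group), function(d)
    data.frame(group = d$group[1], n = nrow(d), mean = mean(d$angle_deg),
               min = min(d$angle_deg), max = max(d$angle_deg))))
  rownames(summ) <- NULL
  list(same = all[all$group == "same", c("junction", "angle_deg")],
       cross = all[all$group == "cross", c("junction", "angle_deg")],
       summary = summ)
}

#' Stress distribution summary
#'
#' Ranges and quantiles of wall shear stress, circumferential stress and
#' the total effective stress tau_T = (tau_w + tau_ref) / tau_e^k_p (the
#' exponentiated net hemodynamic stimulus), split into parent and
#' neo-vessel segments.  tau_T is isolated here so its definition can be
#' swapped.
#'
#' @param net a `vascular_network`.
#' @param state a `flow_state`.
#' @param stimuli output of [compute_stimuli()].
#' @param params an `adaptation_params` (for tau_ref and k_p).
#' @return data.frame with one row per quantity x vessel class.
#' @export
stress_summary <- function(net, state, stimuli,
                           params = adaptation_params()) {
  tau_ref_dyn <- params$tau_ref * MMHG_TO_DYN_CM2
  tau_t <- (stimuli$tau_w + tau_ref_dyn) / stimuli$tau_e^params$k_p
  classes <- ifelse(net$segments$parent, "parent", "neo")
  qs <- function(v) stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  out <- list()
  for (cl in unique(classes)) {
    sel <- classes == cl
    for (nm in c("tau_w", "tau_e", "tau_T")) {
      v <- switch(nm, tau_w = stimuli$tau_w[sel],
                  tau_e = stimuli$tau_e[sel], tau_T = tau_t[sel])
      q <- qs(v)
      out[[length(out) + 1L]] <- data.frame(
        quantity = nm, class = cl, n = sum(sel), min = q[1], q25 = q[2],
        median = q[3], q75 = q[4], max = q[5])
    }
  }
  do.call(rbind, out)
}

#' Export a fraction map: delimited grid plus JSON total
#'
#' @param fm a `fraction_map`.
#' @param path grid output path; `<path>.json` receives the total and ROI.
#' @export
export_fraction_map <- function(fm, path) {
  stopifnot(inherits(fm, "fraction_map"))
  utils::write.table(fm$grid, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(total = fm$total, roi_mm = fm$roi,
                            patches = nrow(fm$grid)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render a network coloured by a segment or node quantity
#'
#' @param net a `vascular_network`.
#' @param state optional `flow_state` (enables "pressure" and "shear").
#' @param color_by "diameter", "order", "pressure" or "shear".
#' @param file optional PNG path; NULL draws on the current device.
#' @export
render_network <- function(net, state = NULL,
                           color_by = c("diameter", "order", "pressure",
                                        "shear"),
                           file = NULL) {
  color_by <- match.arg(color_by)
  if (!is.null(file)) grDevices::png(file, 900, 900)
  segs <- net$segments
  val <- switch(color_by,
    diameter = segs$diameter,
    order = segs$order,
    pressure = {
      stopifnot(!is.null(state))
      (state$pressures[segs$from] + state$pressures[segs$to]) / 2
    },
    shear = { stopifnot(!is.null(state)); state$wall_shear })
  pal <- grDevices::hcl.colors(64, "viridis")
  rng <- range(val)
  idx <- if (diff(rng) == 0) rep(32L, length(val))
    else 1L + floor(63 * (val - rng[1]) / diff(rng))
  graphics::plot(net$nodes$x, net$nodes$y, type = "n", asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = paste("capillary network,", color_by))
  graphics::segments(net$nodes$x[segs$from], net$nodes$y[segs$from],
                     net$nodes$x[segs$to], net$nodes$y[segs$to],
                     col = pal[idx],
                     lwd = pmax(0.5, segs$diameter * 40))
  if (!is.null(file)) grDevices::dev.off()
  invisible(NULL)
}
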