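#' Structural-adaptation parameters
#'
#' Constants of the diameter-update law.  `tau_ref` is stored in mmHg
#' (7.73e-5 mmHg = 0.103 dyn cm^-2); inside the stimulus computation all
#' stresses are expressed in dyn cm^-2, the native units of the
#' circumferential-stress set point (whose formula yields values of order
#' 10-100 dyn cm^-2), so the update's fixed point lands in the
#' physiological wall-shear range.
#'
#' @param tau_ref reference shear offset guarding the log at low shear
#'   (mmHg).
#' @param k_p sensitivity to the pressure (circumferential-stress) signal.
#' @param k_m sensitivity to the metabolic signal.
#' @param k_s basal shrinking tendency.
#' @param haematocrit red-cell volume fraction H, in (0, 1).
#' @param dt dimensionless update step per round.
#' @param d_min,d_max diameter clamps (mm).
#' @param conv_tol convergence threshold on the max relative diameter
#'   change per round.
#' @param max_rounds round limit.
#' @return an object of class `adaptation_params`.
#' @export
adaptation_params <- function(tau_ref = 7.73e-5, k_p = 0.68, k_m = 0.7,
                              k_s = 1.72, haematocrit = 0.45, dt = 0.1,
                              d_min = 0.004, d_max = 0.25, conv_tol = 1e-4,
                              max_rounds = 5000L) {
  stopifnot(tau_ref > 0, k_p > 0, k_m > 0, k_s > 0,
            haematocrit > 0, haematocrit < 1, dt > 0, d_min > 0,
            d_max > d_min, conv_tol > 0, max_rounds >= 1)
  structure(list(tau_ref = tau_ref, k_p = k_p, k_m = k_m, k_s = k_s,
                 haematocrit = haematocrit, dt = dt, d_min = d_min,
                 d_max = d_max, conv_tol = conv_tol,
                 max_rounds = as.integer(max_rounds)),
            class = "adaptation_params")
}

#' Wall-shear stimulus
#'
#' S_tau = log10(tau_w + tau_ref); tau_ref keeps the logarithm finite at
#' vanishing shear.  Unit-agnostic: pass tau_w and tau_ref in the same
#' units.
#'
#' @param tau_w wall shear stress (>= 0).
#' @param tau_ref small positive offset, same units.
#' @return stimulus (log10 units).
#' @export
s_tau <- function(tau_w, tau_ref) {
  stopifnot(all(tau_w >= 0), tau_ref > 0)
  log10(tau_w + tau_ref)
}

#' Circumferential wall-stress set point
#'
#' tau_e(P) = 100 - 86 exp(-5000 [log10(log10 P)]^5.4), a sigmoid of
#' intravascular pressure P in mmHg rising from ~14 toward 100 dyn cm^-2.
#' Pressures are clamped below at `floor_mmHg` to keep the nested logarithm
#' defined.
#'
#' @param pressure intravascular pressure (mmHg).
#' @param floor_mmHg clamp floor (default 10.5 mmHg).
#' @return set-point stress (dyn cm^-2).
#' @export
tau_e_stress <- function(pressure, floor_mmHg = 10.5) {
  p <- pmax(pressure, floor_mmHg)
  100 - 86 * exp(-5000 * (log10(log10(p)))^5.4)
}

#' Pressure stimulus
#'
#' S_P = -log10(tau_e): higher circumferential stress suppresses growth.
#'
#' @param tau_e set-point stress (> 0).
#' @return stimulus (log10 units).
#' @export
s_p <- function(tau_e) {
  stopifnot(all(tau_e > 0))
  -log10(tau_e)
}

#' Metabolic stimulus
#'
#' S_m = log10(Q_ref / (Q_b H) + 1), strongest in low-flow segments; Q_ref
#' is the largest segment flow in the network.  A zero flow is capped at
#' Q_b = 1e-6 Q_ref with a warning.
#'
#' @param q_b segment volumetric flow (>= 0).
#' @param q_ref largest network flow (>= q_b).
#' @param haematocrit H in (0, 1).
#' @return stimulus (log10 units).
#' @export
s_m <- function(q_b, q_ref, haematocrit = 0.45) {
  stopifnot(all(q_b >= 0), q_ref > 0, haematocrit > 0, haematocrit < 1)
  if (any(q_b == 0)) {
    warning("zero-flow segment: metabolic stimulus capped at q_b = 1e-6 q_ref")
    q_b <- pmax(q_b, 1e-6 * q_ref)
  }
  log10(q_ref / (q_b * haematocrit) + 1)
}

#' Per-segment stimuli of a solved flow state
#'
#' Wall shear stress and tau_ref in dyn cm^-2, the pressure for tau_e as
#' the mean of the segment's two node pressures, and Q_ref as the largest
#' absolute segment flow of the current state.
#'
#' @param net a `vascular_network`.
#' @param state a `flow_state`.
#' @param params an `adaptation_params`.
#' @return data.frame with tau_w, tau_e, s_tau, s_p, s_m, bracket per
#'   segment.
#' @export
compute_stimuli <- function(net, state, params = adaptation_params()) {
  segs <- net$segments
  tau_ref_dyn <- params$tau_ref * MMHG_TO_DYN_CM2
  tw <- state$wall_shear                      # dyn cm^-2
  pm <- (state$pressures[segs$from] + state$pressures[segs$to]) / 2
  te <- tau_e_stress(pm)
  q <- abs(state$flows)
  q_ref <- max(q)
  sm <- if (q_ref > 0)
    suppressWarnings(s_m(pmax(q, 1e-6 * q_ref), q_ref, params$haematocrit))
  else rep(0, length(q))
  st <- s_tau(tw, tau_ref_dyn)
  bracket <- st - params$k_p * log10(te) + params$k_m * sm - params$k_s
  data.frame(segment = segs$id, tau_w = tw, tau_e = te, s_tau = st,
             s_p = s_p(te), s_m = sm, q_ref = q_ref, bracket = bracket)
}

#' Diameter increment of the adaptation law
#'
#' Delta D = [S_tau - k_p log10(tau_e) + k_m S_m - k_s] D dt; the updated
#' diameter is clamped to [d_min, d_max].
#'
#' @param diameter current diameter (mm).
#' @param bracket net stimulus (the bracketed sum).
#' @param params an `adaptation_params`.
#' @return list with `delta` and the clamped `diameter`.
#' @export
delta_diameter <- function(diameter, bracket, params = adaptation_params()) {
  delta <- bracket * diameter * params$dt
  list(delta = delta,
       diameter = pmin(pmax(diameter + delta, params$d_min), params$d_max))
}

#' Run structural adaptation to convergence
#'
#' Alternates flow solution and diameter update: each round re-solves the
#' pressures (warm-started from the previous round), recomputes Q_ref and
#' the per-segment stimuli, and updates every non-parent diameter.  Parent
#' vessels stay frozen.  Convergence is declared when the largest relative
#' diameter change over free segments drops below `conv_tol`; if the round
#' limit is hit the best (smallest-change) state seen is returned with
#' `converged = FALSE`.
#'
#' @param net a `vascular_network`.
#' @param flow_params a `flow_params`.
#' @param adapt_params an `adaptation_params`.
#' @param boundary list with `artery` / `vein` node ids.
#' @param diagnostics_every record per-segment diagnostics every k rounds
#'   (0 = final round only).
#' @return list of class `adaptation_run`: `network` (remodelled), `state`
#'   (final `flow_state`), `stimuli` (final), `rounds`, `converged`,
#'   `history` (per-round max relative change), `diagnostics` (long
#'   data.frame).
#' @export
run_adaptation <- function(net, flow_params = angionet::flow_params(),
                           adapt_params = adaptation_params(), boundary,
                           diagnostics_every = 0L) {
  stopifnot(inherits(net, "vascular_network"))
  free <- which(!net$segments$parent)
  parent_d0 <- net$segments$diameter[net$segments$parent]
  state <- solve_pressures(net, flow_params, boundary)
  history <- numeric(0)
  diagnostics <- NULL
  converged <- FALSE
  best <- list(change = Inf, net = net, state = state)
  round <- 0L
  while (round < adapt_params$max_rounds) {
    round <- round + 1L
    stim <- compute_stimuli(net, state, adapt_params)
    if (length(free) == 0L) { converged <- TRUE; break }
    upd <- delta_diameter(net$segments$diameter[free], stim$bracket[free],
                          adapt_params)
    rel_change <- max(abs(upd$diameter - net$segments$diameter[free]) /
                        net$segments$diameter[free])
    net$segments$diameter[free] <- upd$diameter
    history <- c(history, rel_change)
    state <- solve_pressures(net, flow_params, boundary,
                             warm_start = state$pressures)
    if (diagnostics_every > 0L && round %% diagnostics_every == 0L) {
      d <- cbind(round = round, stim,
                 diameter = net$segments$diameter)
      diagnostics <- rbind(diagnostics, d)
    }
    if (rel_change < best$change)
      best <- list(change = rel_change, net = net, state = state)
    if (rel_change < adapt_params$conv_tol) { converged <- TRUE; break }
  }
  if (!converged) { net <- best$net; state <- best$state }
  stim <- compute_stimuli(net, state, adapt_params)
  stopifnot(all(abs(net$segments$diameter[net$segments$parent] -
                      parent_d0) == 0))
  structure(list(network = net, state = state, stimuli = stim,
                 rounds = round, converged = converged, history = history,
                 diagnostics = rbind(diagnostics,
                                     cbind(round = round, stim,
                                           diameter = net$segments$diameter))),
            class = "adaptation_run")
}

#' Export adaptation diagnostics as CSV
#' @param run an `adaptation_run`.
#' @param path output path.
#' @export
export_adaptation_diagnostics <- function(run, path) {
  utils::write.csv(run$diagnostics, path, row.names = FALSE)
  invisible(path)
}
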