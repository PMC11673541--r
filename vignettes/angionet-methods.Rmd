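---
title: "Methods: a hybrid meshless model of sprouting angiogenesis with flow and structural adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid meshless angiogenesis with flow and adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angionet)
```

## Overview

`angionet` simulates sprouting angiogenesis in a chick chorioallantoic
membrane (CAM)-like region of interest, in four coupled stages:

1. **VEGF field** — a meshless radial point interpolation method (RPIM)
   solves the steady-state diffusion equation
   $D_x \,\partial^2\phi/\partial x^2 + D_y\,\partial^2\phi/\partial y^2 + R = 0$
   for the VEGF concentration $\phi$, with a volumetric release $R$ over the
   hydrogel (biomaterial) disk.
2. **Sprouting** — agent-based endothelial tip cells migrate up the VEGF
   gradient with a stochastic angular perturbation, branch at
   order-dependent intervals with CAM-calibrated branch angles, and fuse
   (anastomose) into a capillary graph.
3. **Hemodynamics** — Poiseuille's law per segment,
   $Q = \pi D^4 \Delta P / (128 \mu L)$, and volumetric conservation
   $\sum_k Q_{ck}\beta_k = 0$ at every interior node, solved by successive
   over-relaxation (SOR); wall shear stress is
   $\tau_w = 32 \mu |Q| / (\pi D^3)$.
4. **Structural adaptation** — each segment's diameter follows
   $\Delta D = \big[\log_{10}(\tau_w + \tau_{ref}) - k_p \log_{10} \tau_e
   + k_m S_m - k_s\big]\, D\, \Delta t$, iterated with a re-solved flow
   field until the largest relative diameter change per round falls below a
   tolerance. Parent-vessel diameters stay frozen.

A 5 × 5 mm quantification stage divides the region into a 5 × 5 grid of
square patches and reports, per patch, the projected area fraction covered
by capillaries (clipped segment length × diameter / patch area), plus
branch-angle statistics and stress summaries.

## The RPIM discretisation

The domain is a regular node lattice (default spacing 0.2 mm on the
5 × 5 mm region; any spacing is supported) plus, during growth, the sprout
and tip-cell positions, which enter the nodal cloud so the field resolves
around the advancing front. A background mesh of quadrilateral cells, each
carrying a tensor-product Gauss–Legendre rule (2 × 2 by default), performs
the weak-form integration; the weights sum exactly to the domain area.

At each integration point, the shape function is built over its *influence
domain* — the 16 nearest nodes by default. The radial basis is the
multiquadric $r_i(x) = ((x_i-x)^2 + (y_i-y)^2 + c^2)^p$ with $c = 10^{-4}$
(an absolute length in mm) and $p = 0.9999$, a nearly-linear multiquadric
whose moment matrix is augmented with a single unity row/column so the
shape functions reproduce constants exactly (partition of unity; the
Lagrange multiplier is an unused by-product of the solve). Derivatives are
obtained by differentiating the multiquadric and reusing the same moment
solve. Nearest-node distance ties — frequent on a regular lattice — are
broken by node coordinates (y, then x) rather than by insertion order, so
the assembled system, and hence the solution, is invariant under node
reordering.

Essential (fixed-concentration) boundary conditions are imposed by
row/column elimination, which keeps the reduced system symmetric. In the
CAM-like scenario the parent-vessel edge acts as a zero-concentration sink
and the hydrogel releases VEGF volumetrically ($R = 5\times10^{-4}$ g mm⁻³,
$D = 1.16\times10^{-6}$ mm² s⁻¹), so the gradient points from the parent
vessel toward the biomaterial. A fixed-concentration condition on the
source is also supported but off by default; the reaction (decay)
coefficient $g$ defaults to 0. The unit of $R$ is stated as a
concentration-like density; it enters the balance equation as the source
density, and only the *shape* of the field matters for chemotaxis, since
migration uses the normalised gradient.

Verification: with $D = 1$, $R = 1$ and zero concentration on two opposite
edges, the solver reproduces the closed-form strip solution
$\phi(x) = x(1-x)/2$ (maximum $R L^2 / 8D = 0.125$) to 0.03 % at spacing
0.05 mm, with monotone error decay under refinement.

## Tip-cell migration, branching and anastomosis

Each iteration corresponds to ≈ 6.7 h of CAM development; one step moves a
tip by the distance between its current and previous positions (0.05 mm —
an endothelial cell length — on a sprout's first step). The step direction
is the normalised VEGF gradient rotated by a uniform random angle
$\theta \in [-0.24, 0.24]$ rad (≈ ±13.8°; the perturbation is taken in
radians).

**Directional persistence.** Before the stochastic rotation, the gradient
direction is blended with the tip's previous heading
(`chemo_weight` = 0.1 on the gradient). Endothelial tip cells turn toward
a chemoattractant over several cell lengths rather than instantaneously;
numerically, persistence is what lets a branch daughter carry its imposed
branch angle outward for ~10 steps (~0.4 mm) before aligning with the
gradient. Without it the daughter realigns after a single 0.05 mm step:
branch angles leave no geometric trace, neighbouring sprout trees never
meet, and no perfusable loop can form. With pure chemotaxis
(`chemo_weight = 1`) and a radially symmetric source, a tip's trajectory
is a straight line to the source, and the same holds under persistence
because the blended directions coincide.

**Branching** uses the capillary-order concept (order 1 = highest calibre,
order 3 = lowest by default): a capillary branches when the distance grown
since its last branch strictly exceeds
$d = 0.9286\, e^{-0.219\, O_{cap}}$ mm (0.746 mm at order 1, 0.599 mm at
order 2; the mm reading is consistent with the 5 × 5 mm region). The
daughter takes order $O_{cap}+1$, capped at `max_order`; the parent keeps
its order and resets its odometer. Branch-angle magnitudes are drawn from
a truncated normal centred on the CAM-measured means — 68° when the
daughters share an order (measured range 45–127°), 86° across orders
(range 44–117°) — with σ set so the nearer measured extreme sits at 3σ,
rejection-clipped to the measured range, deflection side random. The
sampler recovers the measured means within sampling error
(≈ ±0.5° at n = 250). A daughter's initial diameter is its parent's × 0.8
per order increment (floor 0.01 mm); adaptation later overwrites all
non-parent diameters, so this choice only seeds the growth stage.

**Anastomosis.** After stepping and branching, any active tip within the
merge radius (0.03 mm) of a node or segment not on its own recent path
(its last two own segments are excluded) is connected there and
deactivated; hits on a segment interior split the segment at the
projection point with an inserted junction node. A step that lands within
the snap tolerance (half a step) of an existing foreign node adopts that
node — the sprout has met another vessel — and likewise fuses. Tips
stepping outside the domain deactivate. Branching is evaluated before
merging within an iteration.

## Hemodynamics

Internally the unit system is mm / s / mmHg, with stresses converted to
dyn cm⁻² (1 mmHg = 1333.22 dyn cm⁻²) for reporting. Blood viscosity is
constant (default 3.5 mPa s, a standard bulk value; the model ignores
Fåhræus–Lindqvist effects). The artery and vein terminals of the parent
vessel carry 45 and 22 mmHg; vessel walls are impermeable (no-flux), so
dead-end sprout tips are natural zero-flow boundaries. The SOR solver
(ω = 1.5) iterates the conductance-weighted nodal averages; convergence is
declared when the largest per-node pressure displacement falls below
`sor_tol` × (p_artery − p_vein). The per-node (rather than globally
scaled) criterion matters because parent and capillary conductances span
four orders of magnitude; with the default `sor_tol` = 1e-12 the SOR
pressures agree with a direct sparse solve to better than
1e-6 × (p_artery − p_vein), and interior pressures always respect the
[22, 45] mmHg discrete maximum principle.

## Structural adaptation

The per-segment stimuli follow the classic structural-adaptation
formulation:

* shear: $S_\tau = \log_{10}(\tau_w + \tau_{ref})$, with
  $\tau_{ref} = 7.73\times10^{-5}$ mmHg = 0.103 dyn cm⁻² guarding the
  singularity at zero shear;
* pressure: $\tau_e(P) = 100 - 86\,\exp[-5000\,(\log_{10}\log_{10} P)^{5.4}]$,
  a sigmoid of the segment's mean intravascular pressure (mmHg) rising
  from ~14 toward 100 dyn cm⁻², entering as $-k_p \log_{10} \tau_e$
  (equivalently $+k_p S_P$ with $S_P = -\log_{10}\tau_e$); pressures are
  clamped at 10.5 mmHg below so the nested logarithm stays defined;
* metabolic: $S_m = \log_{10}(Q_{ref}/(Q_b H) + 1)$ with haematocrit
  $H = 0.45$ and $Q_{ref}$ recomputed every round as the largest segment
  flow; zero flows are capped at $10^{-6} Q_{ref}$;
* constants $k_p = 0.68$, $k_m = 0.7$, $k_s = 1.72$ (the shrinking
  tendency).

All logarithms are base 10 — the base the constants were calibrated in; a
regression test pins this, since changing the base silently rescales every
constant. **Units of the stimuli:** inside the bracket, $\tau_w$ and
$\tau_{ref}$ are expressed in dyn cm⁻², the native scale of the $\tau_e$
formula. This is the only consistent reading: with stresses in mmHg the
bracket's fixed point sits at $\tau_w \sim 10$–200 mmHg
(10⁴–10⁵ dyn cm⁻²), three orders of magnitude above any physiological
wall-shear value, whereas the dyn cm⁻² reading puts equilibria in the
tens of dyn cm⁻².

Each round: solve flow (warm-started), compute stimuli, update all
non-parent diameters by $\Delta D$ (Δt = 0.1, dimensionless — the bracket
is a pure number, so Δt absorbs the scale), clamp to
[d_min, d_max] = [0.004, 0.25] mm, stop when the largest relative change
drops below `conv_tol` = 1e-4 (equivalently |bracket| < 10⁻³ on free
segments) or after `max_rounds` = 5000, returning the best state with a
`converged` flag. Parent diameters (0.17–0.2 mm, drawn per scenario) are
bit-identical before and after. Adaptation is fully deterministic.

### Behaviour of the fixed point

At equilibrium
$\log_{10}\tau_w \approx k_p \log_{10}\tau_e + k_s - k_m S_m$: a segment's
settled wall shear is controlled by how small its flow is relative to
$Q_{ref}$ (carried by the parent vessel). Segments carrying less than
~$Q_{ref}/150$ settle below ~13 dyn cm⁻²; the dominant anastomotic loop
of a sparse, desk-scale network (30 growth iterations from 3–6 tips)
self-consistently converges to a few percent of $Q_{ref}$ and therefore to
~40–70 dyn cm⁻². Reaching the low-shear regime throughout requires the
dense CAM-scale plexus — many parallel loops sharing flow over long,
tortuous paths — not just more adaptation rounds. Before adaptation, with
capillary-sized diameters, neo-vessel wall shear in the generated networks
does lie in the 0.1–13 dyn cm⁻² band. The stability of the fixed point
also depends on topology: a free path shunting part of a parent vessel is
stable (its flow scales as $D^4$ at pinned pressure drop, so $S_m$ falls
steeply), whereas a free segment in series with the whole circuit has its
$Q_{ref}/Q_b$ ratio pinned and drifts to the diameter clamp.

## The synthetic CAM-like scenario

`generate_cam_like_scenario()` emulates the quantified region of interest:
a 5 × 5 mm domain; the hydrogel source disk centred on the lower-left
corner (radius 1.5 mm — the corner portion of an 8 mm-diameter hydrogel
that falls inside the ROI); a parent vessel spanning the opposite (top)
edge, diameter drawn uniformly in [0.17, 0.2] mm, artery terminal at the
left end and vein at the right; and 3–6 initial tip cells attached to
parent nodes at uniform positions in x ∈ [0.75, 4.25] mm (initial sprout
diameter 0.02 mm, a typical capillary calibre). All draws come from named
substreams ("scenario", "migration", "branching") of one master seed, so
adding a consumer of randomness does not perturb existing trajectories,
and a fixed seed reproduces the network bit-identically.

What the generator does *not* emulate: real CAM image-derived tip
positions and parent geometries, interdigitating artery/vein trees, ECM
heterogeneity, oxygen/hypoxia coupling, and the image-processing
(NeuronJ-style) digitisation step. Tests passing on synthetic scenarios
therefore validate the numerics and the calibrated stochastic laws, not
agreement with any particular CAM photograph.

## Numerical choices and degenerate inputs

* Problem sizes: the default scenario uses a 26 × 26 node lattice
  (spacing 0.2 mm), 25 × 25 integration cells × 4 Gauss points, and grows
  to ~200–300 segments in 30 iterations — sizes chosen so a full
  grow/flow/adapt/quantify pipeline completes in minutes on one CPU while
  the strip benchmark demonstrates the discretisation error is already
  far below the model's parametric uncertainty.
* Zero VEGF gradient at a tip: reuse the previous direction; a tip with
  neither is deactivated.
* Coincident nodes would make the radial moment matrix singular; network
  nodes are only added to the RPIM cloud if they are farther than
  min(5 µm, spacing/4) from every existing node.
* A singular moment matrix or an unconstrained pressure/diffusion system
  raises an error naming the point or the missing boundary condition.
* Patch clipping uses half-open parametric clipping, so shared patch
  edges are never double-counted and the 5 × 5 decomposition reproduces
  the whole-ROI fraction exactly.
* The total effective stress is defined as
  $\tau_T = (\tau_w + \tau_{ref}) / \tau_e^{k_p}$ — the exponentiated net
  hemodynamic stimulus. The quantity is conventional rather than uniquely
  determined; it is isolated in `stress_summary()` so the definition can
  be swapped.

## Known limitations

2D only; steady-state (not transient) VEGF; constant Newtonian viscosity
and uniform haematocrit (no phase separation at bifurcations); no
stalk-cell mechanics or tip/stalk phenotype switching; no conducted
metabolic signalling; vessels shrink to `d_min` but are never pruned from
the graph; no oxygen field. The periodic lateral wrap for tip migration is
not applied to the flow problem.
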