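---
title: "From noisy centerlines to uncertainty-aware 1D hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From noisy centerlines to uncertainty-aware 1D hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasctrees)
```

## The problem

Patient-specific 1D blood-flow models are built on vascular networks
extracted from CT or MR images: a segmentation produces a 3D surface, a
centerline extractor places maximally inscribed spheres along each
vessel, and the result is a set of ordered 3D point sequences, each
point carrying the local inscribed-sphere radius.  Two systematic flaws
of this chain propagate straight into hemodynamic predictions:

* **junction nodes land upstream of the ostium** — where inscribed
  spheres of a parent and its daughters first intersect, not where the
  vessels anatomically divide, so the daughters' first nodes run nearly
  coincident and their radii mix parent and daughter lumens;
* **the per-node radii are unreliable near junctions and near the
  image-resolution limit**, so summarizing a vessel by the mean of all
  its nodes biases the radius that the flow model sees — and flow
  resistance scales like \(r^{-4}\), so small radius errors are large
  pressure errors.

`vasctrees` turns such centerlines into *labeled directed trees* (root /
central / terminal vessels plus a parent-daughter connectivity map),
repairs the junctions, extracts a representative radius per vessel with
an uncertainty estimate, appends self-similar structured trees below the
image resolution, solves the nonlinear 1D blood-flow equations on the
result, and propagates the radius uncertainty to pressure and flow by
Monte Carlo sampling.

## Junction relocation

For each junction, the node-wise distance between the two daughters
(the closest pair, at a trifurcation) is
\(D_i = \lVert x_{d_1,i} - x_{d_2,i}\rVert\), \(i = 1..N\), with \(N\)
the node count of the shorter daughter.  The new junction index is the
first \(i\) with \(D_i/D_{\max} > 0.1\); the nearly coincident daughter
prefixes are replaced by their node-wise average, appended to the
parent; and daughter nodes in the band
\(0.1 < D_i/D_{\max} \le 0.2\) are smoothed toward the extended parent
path by the weighted average \((w\,x_d + x_p)/(w+1)\).  The cutoffs
(0.1, 0.2) and the weight \(w\) (2 for rapidly branching pulmonary-like
networks, 100 for aorta-like ones) are empirical inputs, exposed in
`junction_adjust_params()`.  As printed, the weight multiplies the
*daughter* term; because a large \(w\) therefore favors the daughter
path, a `weight_target` switch is provided to invert the convention
rather than silently second-guessing it.  Junctions are processed from
the terminal-most junctions toward the root.

Two bookkeeping choices are deliberate: the averaged prefix nodes carry
the averaged radii (those nodes lie in the ostium and are excluded from
radius estimation anyway), and each daughter keeps its node at the new
junction index while the parent gains the averaged copy, so the parent
gains exactly \(k\) nodes and each daughter drops exactly \(k-1\).

## Change points and the optimal radius segment

A vessel's radius sequence is segmented in two steps, mirroring the
two-package workflow common in applied change-point work:

1. **How many change points (0–3)?**  Binary segmentation under an
   independent-Gaussian model with segment-specific mean and variance;
   a split is accepted only if it lowers
   \(\mathrm{BIC} = -2\log L + 2\,(\#\text{segments})\log n\).
   The count is capped at three: the structures worth modeling are the
   ostium bump, the usable plateau, and a resolution-limited tail.
   *Numerical choice:* segment variances are floored at a robust global
   noise estimate (the median absolute successive difference, scaled).
   Without the floor, a chance low-variance stretch of pure noise makes
   the mean/variance cost reward arbitrary splits; with it, a constant
   noisy vessel is reliably assigned zero change points and a clean
   step exactly one.
2. **Where exactly?**  The continuous broken-line model
   \(r = \beta_0 + \beta_1 x + \sum_i d_i\,(x-\psi_i)_+\) is fitted by
   iterative linearization around the current breakpoints (working
   covariates \(U_i = (x-\psi_i)_+\) and \(V_i = -I(x>\psi_i)\), each
   breakpoint updated by the ratio of the \(V\) and \(U\) coefficients,
   with step halving).  Because weakly identified breakpoints have
   near-tied local optima, the iteration is run from a small
   deterministic set of quantile starts, screened against a coarse
   integer lattice, and finished by a local integer polish; an
   exhaustive grid search is the flagged fallback on non-convergence.
   On sequences of the sizes this package sees (tens to a couple of
   hundred nodes) the result matches the exhaustive least-squares
   optimum in well over 95% of seeded cases.

The **optimal radius segment** \(r_{\mathrm{opt}}\) is then chosen by
case rules.  Non-tapering vessels: the flattest section after the first
change point if it holds more than 25% of the nodes (Case 1); otherwise
a start/end rule — start at \(\psi_1\) if it lies beyond the 25% mark,
else at \(\psi_2\) unless that is past the midpoint, in which case the
25% mark; end at \(\psi_m\) or \(n\) according to the slope ratio
\(s_a = |slp_{m+1}-slp_m|/|slp_m|\) against \(\xi = 2.8\) (Case 2);
whole vessel when no change point exists (Case 3).  Tapering vessels
use the longest section (threshold 40%) instead of the flattest, fall
back to the same Case 2, keep Case 3 constant, and anchor an
exponential at \(r(1)\) and \(r(n)\) when all else fails (Case 4).
The section before the first change point is never selected — that is
the ostium-exclusion property the whole construction exists for.
Segment fractions are measured in node count (nodes are near
equispaced).  The slope ratio uses absolute values; a signed ratio is
meaningless as a threshold.  Both the branch direction of the end rule
and the absolute-value convention are switchable in
`selection_params()` for sensitivity analysis.

The representative radius is the mean over \(r_{\mathrm{opt}}\)
(constant vessels) or the least-squares fit of
\(\hat r(s) = r_{\mathrm{in}}\exp(s\log(r_{\mathrm{out}}/r_{\mathrm{in}}))\),
\(s \in [0,1]\) across the segment (tapering; Nelder-Mead from the
endpoint radii, non-positive iterates rejected).  Its standard
deviation is the root-mean-square residual
\(\sigma = \sqrt{\tfrac1k\sum_i (r_i - \hat r_i)^2}\) — the only
reading of the dispersion formula that carries units of cm.

**Consistency check.**  Healthy networks satisfy \(r_p > r_d\) and
\(\sum A_d > A_p\) at each junction.  A violating *terminal* daughter
at a bifurcation is reassigned \(r_d = \alpha r_p\) (one violator) or
\((\alpha, \beta) r_p\) (a pair), and tagged with the scale
\(\kappa = r_d/r_p\) for the sampler; internal-vessel and trifurcation
violations, and area violations, are reported for manual review, not
auto-fixed.

## Structured trees and the viscosity of blood in microvessels

Below image resolution, each terminal vessel is extended by an
asymmetric self-similar tree: daughters scale the parent radius by
\(\alpha\) and \(\beta\) (\(\alpha,\beta<1\), \(\alpha+\beta\ge 1\)),
lengths are \(\ell_{rr}\, r\), and the recursion stops at
\(r_{\min} = 10\,\mu\mathrm m\) (a red cell diameter); a vessel is
generated only if its radius is at least \(r_{\min}\) (pre-check
semantics, configurable), which makes the extreme-path depths exact
geometric sequences — e.g. a 0.01 cm root with \(\alpha = 0.88\)
supports 18 pure-\(\alpha\) generations above \(r_{\min}=0.001\) cm.

Apparent blood viscosity falls in microvessels before recovering
toward the bulk value (the Fåhræus–Lindqvist effect).  The law used is
\(\mu_S = (\mu_L/3.2)\,D\,[1 + D(\eta(r)-1)]\) with
\(\eta(r) = 6e^{-0.17 r} + 3.2 - 2.44 e^{-0.12 r^{0.645}}\) (relative
viscosity at hematocrit 0.45) and the plasma-layer correction
\(D = 2r/(2r - 1.12)\), with \(r\) in micrometres — the 1.12 µm
constant only makes sense at the plasma-layer scale, so radii are
converted from cm internally.  The grouping is isolated in
`small_vessel_viscosity()`; it recovers \(\mu_S \to \mu_L\) exactly as
the diameter grows.

## Two-domain hemodynamics

**Large vessels** solve mass and momentum balance for a compliant
axisymmetric vessel,
\[
A_t + q_x = 0,\qquad
q_t + \left(\frac{q^2}{A}\right)_x + \frac{A}{\rho}p_x
  = -\frac{2\pi\nu R}{\delta}\,\frac{q}{A},
\]
with a flat velocity profile and a boundary layer of thickness
\(\delta = \sqrt{\nu T/2\pi}\) (the radical is required for \(\delta\)
to carry cm), friction evaluated at the deformed radius
\(\sqrt{A/\pi}\) (switchable to the rest radius), and the elastic wall
law \(p - p_0 = \tfrac43\frac{Eh}{r_0}(\sqrt{A/A_0}-1)\) with
\(Eh/r_0 = k_1 e^{k_2 r_0} + k_3\).  The pressure-gradient term is
written in flux form \(B = f A^{3/2}/(3\rho\sqrt{A_0})\) plus an
analytic geometric source for tapering vessels (verified against a
finite-difference identity in the tests).  Interior points advance by
the two-step (Richtmyer) Lax–Wendroff scheme; the time step is fixed at
a fraction (`cfl_safety`, default 0.5) of the CFL bound and the run
restarts with a halved step if the bound is ever violated.

Boundaries close the hyperbolic system through its Riemann quantities
\(W_\pm = u \pm 4c\), \(c = \sqrt{f/2\rho}\,(A/A_0)^{1/4}\): the root
takes a prescribed periodic inflow; junctions solve pressure continuity
and flow conservation together with the outgoing characteristics of all
connected vessels by damped Newton iteration (residuals at machine
precision, so junction flow imbalance is \(10^{-10}\)-level); outlets
couple to an impedance kernel.  Characteristic foot points are
interpolated quadratically and integrated with a Heun
predictor–corrector, which keeps the scheme second-order accurate
overall — the observed convergence order on a smooth single-vessel
fixture is ≈ 2.  Waveforms with derivative kinks (a half-sine systole
ending abruptly) degrade the *observable* order, as for any
shock-capturing-free scheme, so grid-convergence studies use the
infinitely smooth `"sine"` inflow shape.

**Small vessels** are solved per frequency: the linearized momentum
equation carries the Womersley factor
\(F_J = 2J_1(w_0)/(w_0 J_0(w_0))\) with
\(w_0^2 = i^3 r_0^2\omega/\nu\) (the square on \(r_0\) is required
dimensionally), wave speed \(c = \sqrt{A_0(1-F_J)/(\rho C_A)}\) and
admittance \(g = cC_A\), \(C_A = \tfrac32 A_0/(Eh/r_0)\) — the unique
choices that make the inlet–outlet impedance map the transmission-line
solution of the linearized system.  \(J_1/J_0\) at complex argument is
evaluated by a Lentz continued fraction (no installed package provides
complex Bessel functions); it is overflow-free at any Womersley
number.  At \(\omega = 0\) the exact Poiseuille limit
\(Z = 8\mu_S \ell/(\pi r_0^4) + Z_L\) is used.  Junctions combine
daughters in parallel admittance and the self-similar tree is traversed
once per distinct \((\alpha^j\beta^k)\) scale with memoization.  The
root spectrum becomes a periodic time-domain kernel by inverse DFT on
the solver's own time grid; modes above `n_modes` (default 128) are
filled with the *real part* of the last evaluated mode — the
high-frequency limit of a transmission line is its real characteristic
impedance, and carrying the reactive part across the tail band makes
the discrete boundary condition non-passive.  Structured-tree leaves
see zero terminal impedance (pure outflow) unless configured otherwise.
Internally everything is CGS; pressures are reported in mmHg
(1 mmHg = 1333.22 g cm⁻¹ s⁻²), and the reference pressure \(p_0\)
defaults to 0, i.e. pressures are read relative to the outflow
reference.

## Uncertainty propagation

Each vessel's radius gets the normal law \(N(\hat r, \sigma^2)\);
reassigned vessels draw from \(N(\kappa\hat r_p, \kappa\sigma_p^2)\)
(variance scaled by \(\kappa\), as specified; a switch scales the sd
instead).  Draws are independent across vessels and samples,
non-positive draws are rejected and redrawn, tapering vessels are
scaled by a single factor preserving their taper ratio, and the
parent/daughter order violations that independent sampling can produce
are counted per sample, not corrected.  Descriptive statistics — the
coefficient of variation \(\sigma/\hat r\), Gaussian kernel densities
of radius distributions, vessel-wise one-way ANOVA across repeated
segmentations — use the standard `stats` machinery, and ensemble
solutions are summarized by midpoint pressure/flow range, minimum and
maximum per member plus the cross-member envelope.

## What the synthetic fixtures emulate — and what they do not

All tests run on seeded generators with exact ground truth:
`make_synthetic_vessel()` produces an ostium bump (flat at
`ostium_scale`, then a short ramp) ahead of a constant or exponentially
tapering plateau with Gaussian radius noise; `make_synthetic_network()`
grows a bifurcating (optionally once-trifurcating) network with
scaling-law radii, node spacing 0.05 cm, daughters that share the
junction node and separate quickly before drifting apart gently, and a
centerline-extraction flaw injected by truncating the parent
`junction_offset` nodes early and prepending near-coincident, slightly
inflated prefixes to the daughters — which is what inscribed-sphere
centerlines actually produce.  These fixtures capture the *structure*
of the artifacts, not their full messiness: real centerlines also carry
curvature, surface-irregularity oscillations correlated along the
vessel, anisotropic voxel noise, and occasional spurious branches.
Passing tests demonstrate that each algorithm recovers known truth
under controlled versions of the artifacts it targets, not that any
particular clinical dataset is reproduced.

A worked end-to-end example:

```{r example, eval = FALSE}
net <- make_synthetic_network(levels = 3, root_radius = 0.4,
                              junction_offset = 5, noise_sd = 0.01, seed = 1)
wf <- make_inflow_waveform(0.85, 10 * 0.85 * 0.4)
cfg <- pipeline_config("pulmonary", grid = 12L, cycles = 6L)
res <- run_pipeline(net$centerlines, wf, cfg, out_dir = "run1")
res$reports$radii
midpoint_series(res$solution, "R")
```

## Problem sizes and numerical settings

Defaults are sized for routine desk use: 24 grid points per vessel, at
most 10 cardiac cycles with early stopping at a period-to-period change
of \(10^{-3}\), 128 impedance modes, CFL safety 0.5.  The shipped tests
and the acceptance script use coarser grids (9–16 points), 3–7-vessel
networks with structured-tree outflow and a 511-vessel topology for
sampling statistics; these sizes were chosen so each study isolates one
mechanism and completes in seconds to a couple of minutes while leaving
the measured properties (oracle equivalence, conservation, convergence
order, coverage) unambiguous.  The steady-flow benchmark sets the
vessel radius to \(4\delta\), the radius at which the boundary-layer
friction coefficient coincides exactly with the Poiseuille law, so the
analytic prediction it is compared against is exact rather than
approximate.

## Known limitations

* The junction smoothing is the band-limited weighted average only; no
  curvature-based fairing.
* Case rules treat "25% of observations" in node count; strongly
  non-uniform node spacing would warrant arc-length weighting.
* The solver assumes periodic inflow, rigid junction positions, and a
  single inlet; collapse (\(A \to 0\)) is detected, not modeled.
* Sampling is independent across vessels; daughters can exceed parents
  in individual draws (counted, not corrected), and covariance-aware
  sampling is out of scope.
* The structured-tree leaf impedance is a configurable constant (zero
  by default), not a microcirculation model.
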