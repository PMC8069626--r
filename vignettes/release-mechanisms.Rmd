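---
title: "Mechanism-decomposed modelling of drug release"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism-decomposed modelling of drug release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relkin)
```

## The model

Release of a dissolved drug from a thin, non-degradable polymer film rarely
follows a single rate law. `relkin` models the cumulative fraction released
`Mt/M∞` as a convex combination of three mechanism curves,

$$\frac{M_t}{M_\infty}(t) \;=\; \mu_1 F_1(t) + \mu_2 F_2(t) + \mu_3 F_3(t),
\qquad \sum_i \mu_i = 1,\; 0 \le \mu_i \le 1,$$

where the weights $\mu_i$ are the fractions of the total load delivered by
each mechanism and each $F_i$ is normalised to run from 0 toward 1:

* **Burst** — drug at or near the film surface dissolves quickly;
  first-order kinetics give $F_1(t) = 1 - e^{-k_b t}$ with burst constant
  $k_b$ (h⁻¹).
* **Fickian diffusion** — drug trapped in the matrix diffuses out through
  the polymer network. For a plane sheet of thickness $h$ under sink
  conditions, with uniform initial loading,
  $$F_2(t) = 1 - \frac{8}{\pi^2}\sum_{n=0}^{\infty}
  \frac{1}{(2n+1)^2}\exp\!\Big(\!-\frac{(2n+1)^2\pi^2 D_e t}{h^2}\Big),$$
  with effective diffusivity $D_e$ (m²/h). Only odd indices $2n+1$ appear:
  the even cosine modes of the initial condition vanish, and the odd
  reciprocal squares sum to $\pi^2/8$, which is exactly what makes
  $F_2(0)=0$. (Summing over *all* integers, as this expression is sometimes
  typeset, would give $F_2(0) = 1 - (8/\pi^2)(\pi^2/6) = -1/3$; the
  odd-index form is the standard plane-sheet solution and is what the
  package implements.) The early-time expansion of the same solution is the
  square-root law $M_t/M_\infty \approx 4\sqrt{D_e t/(\pi h^2)}$, reliable
  up to roughly 60 % release — `diffusion_early_approx()` warns beyond
  that. The length scale is the full film thickness, 2 mm by default.
* **Osmotic pumping** — water drawn across the semi-permeable polymer by
  the osmotic pressure gradient $\Delta\pi$ expels dissolved drug at a
  constant rate: $F_3(t) = k_{os}\,t$ with
  $k_{os} = \gamma\,\Delta\pi$. The factor
  $\gamma = A h K' S / M_\infty$ lumps film area, thickness, membrane
  permeability, drug solubility and loaded mass; these are rarely all
  measured, so the package defaults to $\gamma = 1.111$ h⁻¹atm⁻¹ — chosen
  so that a representative gradient of 0.009 atm corresponds to a
  zero-order slope completing release in about 100 h — and every reported
  $\Delta\pi$ states the $\gamma$ it was derived with. Supplying
  `geometry_constants()` replaces the default by the physical product.

The composite is **not clamped at 1** by default: $F_3$ grows without
bound, and inside the fitted window the weights keep the curve physical.
Long-horizon simulation can opt into clamping (`clamp = TRUE`).

### Membrane physics

The osmotic picture is backed by porous-membrane hydraulics: the Poiseuille
pressure drop $\Delta P = 8\eta\delta J_v/(n\pi a^4)$ across $n$ cylindrical
pores of radius $a$, its inverse, the hydraulic permeability
$L_p = n\pi a^4/(8\eta\delta)$ (so $J_v = \Delta P\,L_p$ identically), and
the reflection coefficient $\sigma = (1-(1-\phi)^2)^2$ computed from the
solute-to-pore radius ratio $\phi \in [0,1]$. $\sigma$ is taken as a purely
geometric quantity; the interpretation as a ratio of observed to ideal
osmotic pressure is not modelled separately. Zero-order osmotic release
presumes $\Delta\pi \gg \Delta P$; `osmosis_dominance_check()` verifies
this with a configurable dominance factor (default 10; 1 atm = 101 325 Pa).
A WLF-type free-volume coefficient $f_g = B\,\Delta\alpha\,A/2.303$ is
provided for relating polymer free volume to the osmotic behaviour; its
inputs are user-supplied.

## Fitting

`fit_release()` estimates $X = (\mu_1,\mu_2,\mu_3,k_b,D_e,k_{os})$ by
minimising the unweighted sum of squared residuals subject to the simplex
equality $\sum\mu_i=1$, box bounds on every parameter, and an ordering
inequality described below. All three weights are kept as explicit
parameters with the equality constraint (rather than eliminating one),
which keeps the constraint machinery honest and the multipliers
interpretable.

The constrained problem is solved by the package's own SQP engine:

1. linearise the constraints at the current iterate and solve a strictly
   convex QP subproblem (primal active-set method over the KKT system) for
   a search direction and multiplier estimates;
2. backtracking line search (factor 0.5, sufficient decrease 1e-4) on an
   $\ell_1$ exact-penalty merit function whose penalty parameter tracks
   the largest multiplier;
3. damped BFGS update of the Lagrangian Hessian approximation (Powell
   damping at $s^\top y \ge 0.2\, s^\top H s$, initial $H = I$, updates
   that would make $H$ numerically singular are skipped);
4. stop when the KKT residual — the max norm over stationarity, primal and
   dual feasibility, and complementarity — falls below the tolerance.

The solver default tolerance is 1e-4, the classical acceptance value for
this scheme; the fitter tightens it to 1e-10 so that recovered parameters
are accurate to far below 0.1 %. Gradients are forward finite differences
(relative step 1e-7) unless an analytic gradient is supplied; the fitter
supplies the analytic least-squares Jacobian, including the term-wise
derivative of the diffusion series. Because the admissible $D_e$ range
spans seven decades (1e-12 to 1e-5 m²/h), $D_e$ is optimised as
$\log_{10} D_e$ internally and reported on the natural scale.

**Multistart.** The objective is multimodal, so the fit launches from a
deterministic grid: all simplex-lattice weight combinations of resolution
2 plus the centroid (7 points), crossed with 2 log-spaced kinetic tuples
taken at interior points of the bounds — 14 starts. The grid is a pure
function of the settings; optional random starts draw from a recorded
seed. The multistart stops early once a start reaches an essentially
perfect fit (SSE ≤ 1e-14), and the returned solution is always at least as
good as every explored start.

**Identifiability.** The burst curve and the leading mode of the diffusion
series are both saturating exponentials, so under observation noise the
two mechanisms can swap roles: a fit with a slow "burst" ($k_b$ near the
diffusion relaxation rate) and a fast "diffusion" term can reach a
marginally lower residual while scrambling the mechanism labels — the
label-switching problem familiar from mixture models. The fitter therefore
imposes the ordering constraint $k_b \ge \pi^2 D_e/h^2$ (the burst must
relax at least as fast as the slowest diffusion mode) by default
(`order_constraint`). The constraint is far from active at all built-in
parameter sets, so it does not affect noiseless recovery; it only removes
the swapped, physically meaningless branch. Even so, $k_b$ is intrinsically
weakly identified when the burst saturates between the first two sampling
points, and $D_e$ when little of the diffusion curve saturates inside the
window: on the default grid at noise sd 0.01, the median relative errors of
the refitted $k_b$ and $D_e$ coincide with the Cramér–Rao bound of the
generating conditions (roughly 5–30 % depending on the condition). The test
suite asserts exactly that — estimator efficiency relative to the
information bound — because no estimator can do better under those
conditions.

**Degenerate inputs.** Fits require at least 6 points; observed fractions
must lie in [0, 1.2] (cumulative data can overshoot 1 through noise, and
the unclamped osmotic term itself carries the strongest built-in condition
to ≈1.08 at 100 h); a zero-variance profile is rejected (its $R^2$ is
undefined and every kinetic constant would sit at a bound). Fractions are
accepted above 1 deliberately — truncating them would bias the noise.

## Synthetic data

`generate_profile()` produces the composite forward curve on a grid plus
i.i.d. Gaussian noise on the fraction scale, clipping negatives at zero
(values above 1 are kept, as in real cumulative data). Defaults — 0–100 h,
101 points, noise sd 0.01 — cover the burst (hours), osmotic (tens of
hours) and diffusion (days) regimes of the built-in parameter sets; the
noisy-refit checks use sd 0.02, matching the ≈0.02 RMSE scale the
reference fits report. What the generator deliberately does *not* emulate:
inter-replicate variability in the underlying parameters, irregular or
sparse sampling times, and autocorrelated measurement error (cumulative
assays re-measure the same medium). Passing recovery tests on this
generator therefore demonstrates correctness of the estimator under the
model's own assumptions, not robustness to real-world artefacts.

The five built-in conditions (`builtin_conditions()`) are fitted parameter
sets for diclofenac release from 2 mm polyurethane films — drug loads of
10/20/30 % w/w at 7.5 mL/s flow and flow rates of 0/7.5/23.5 mL/s at 20 %
load. They serve as generator defaults and recovery targets; their weight
rows each sum to exactly 1.

## Correlations and prediction at unseen conditions

Fitted constants are linked to drug load $C$ by the Arrhenius-type form
$\ln k = a + b\,(1/C)$ and to flow rate $Q$ by the linear form
$k = a + b\,Q$. Both classical one-parameter versions ($\ln k = b/C$,
$k = b\,Q$) are available behind `intercept = FALSE`, but the default keeps
the intercept: a zero-intercept line cannot pass through a nonzero constant
at $Q = 0$ (the static condition has $k_b = 1.7$ h⁻¹), and the
one-parameter log form is equally over-constrained. Predictions are
evaluated on the natural scale (exponentiated for the concentration form),
warn outside a configurable extrapolation band, and are combined with
mechanism weights linearly interpolated in the varied factor and
renormalised to the simplex — the weights at an unseen condition are not
refit, an assumption that is exact at the training knots and first-order
accurate between them. At a training knot with two-point (exactly
interpolating) correlations, the predicted profile reproduces the direct
forward simulation to below 1e-9.

## Numerical choices

* Diffusion series: truncated when the next term falls below `tol`
  (default 1e-12), hard cap 10 000 terms; verified against a fixed
  10 000-term reference sum. At times so small that the cap binds the
  series is polynomially slow; $t = 0$ is returned exactly.
* QP subproblems: feasibility by least-norm projection plus violated-
  constraint repair, then primal active-set iteration; inconsistent
  linearisations raise an infeasible-subproblem error, which the outer
  loop answers with a ridge-regularised restoration step.
* Bounds are passed to the QP as general inequalities (uniform handling,
  ordered after user inequalities: lower bounds, then upper).
* Tie-breaks: among multistart runs the lowest final objective wins;
  equality of objectives keeps the earliest start (determinism).
* All pressure arithmetic is in Pa internally; atm appears only at the
  interfaces (1 atm = 101 325 Pa).

## Problem sizes used in the checks

The shipped checks fit 101-point profiles: five noiseless refits (one per
built-in condition), 20 noisy replicates at sd 0.02 for the fit-quality
metrics, and 20 replicates at sd 0.01 for the efficiency check — about a
minute of computation in total, chosen to keep the full suite quick while
leaving the medians stable to well within their asserted margins.

## Known limitations

* The model assumes constant $D_e$, no swelling or degradation, perfect
  sink conditions and an always-saturated osmotic driving force; systems
  violating these need different mechanism terms.
* $k_{os}$ and $\mu_3$ enter the likelihood only through their product and
  through the simplex constraint; $\Delta\pi$ is only as meaningful as the
  $\gamma$ it is reported under.
* The SQP engine targets small, dense, smooth problems (tens of
  parameters); it makes no global-optimality claims beyond the multistart
  coverage and is not built for sparse or nonsmooth work.
* Correlation-based prediction interpolates three support points per
  factor; extrapolating far outside the studied 10–30 % load or
  0–23.5 mL/s flow ranges is unsupported.
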