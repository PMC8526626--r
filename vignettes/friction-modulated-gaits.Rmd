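---
title: "Friction-modulated gaits: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Friction-modulated gaits: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

`frictiongait` treats a limbless body as an inextensible planar curve
of unit length whose *shape* is prescribed and whose *placement* —
centre of mass $\bar x(t)$ and mean orientation $\bar\alpha(t)$ — is
dynamic. Two traveling waves define the actuation template:

* a lateral curvature wave
  $\kappa(s,t) = \epsilon\cos(2\pi k(s+t))$, and
* a lifting wave
  $\hat N(s,t) = \max\{0,\, A\cos(2\pi\lambda k(s+t+\Phi)) + 1\}$,

with arclength $s\in[0,1]$ running tail to head and time measured in
undulation periods. The lifting wave does not move material out of the
plane; it models the *effect* of lift as a traveling redistribution of
normal force, renormalized at every instant
($N = \hat N / \int_0^1 \hat N\,ds$) so the body's total weight is
conserved. This is the central modeling reduction: 3D gait components
and even substrate features act on the planar dynamics only through the
local magnitude of friction.

Shape placement uses the mean-zero integration operator
$I[f](s) = \int_0^s f\,ds' - \int_0^1\!\!\int_0^{s} f\,ds'\,ds$:
orientations are $\alpha = \bar\alpha + I[\kappa]$ and positions
$x = \bar x + I[\mathbf t]$, which makes the quadrature means of
$\alpha(s)$ and $x(s)$ equal $\bar\alpha$ and $\bar x$ by construction.
Ground reaction is anisotropic Coulomb friction with coefficients
(relative to forward) $\mu_t/\mu_f$ transverse and $\mu_b/\mu_f$
backward, split by a Heaviside function of the tangential sliding
direction. Newton's equations for $\bar x$ and $\bar\alpha$ follow by
integrating the force balance along the body under the assumption that
internal forces have zero net force and torque; the angular equation
carries an inertial correction term
$\int I[\mathbf n]\cdot I[\mathbf t(\bar\alpha_t + I[\kappa_t])^2] -
I[\mathbf t]\cdot I[\mathbf t I[\kappa_{tt}]]\,ds$ that arises from
differentiating the shape reconstruction twice in time. We re-derived
this equation from the force balance (expand $x_{tt}$ through the
reconstruction, cross with $x-\bar x$, use the internal-force
assumptions) rather than transcribing it, and validate the assembled
form in the test suite against a finite-difference oracle that knows
nothing of the assembly: it differentiates the velocity reconstruction
numerically and solves the raw torque balance (agreement to 1e-4
relative, dominated by the oracle's difference step).

Static friction is omitted: the velocity regularization (below) lets
nodes pass smoothly through zero speed, and steady-state behaviour is
insensitive to this choice.

## Parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `epsilon` | lateral curvature amplitude | 7 | strongly curved S-shape typical of slithering kinematics |
| `k` | lateral wavenumber (waves/body length) | 1 | one full wave on the body |
| `A` | lifting amplitude | 0 | planar gait unless lifted |
| `phi` | lifting phase offset (turns) | 0 | scanned over [0, 1) in phase maps |
| `lam` | lifting/lateral wavenumber ratio | 1 | one-sided (sidewinder-like) lifting |
| `mu_t_ratio` | transverse/forward friction | 2 | firm-ground value measured on real snakes; a lower bound since snakes actively increase grip |
| `mu_b_ratio` | backward/forward friction | 1.5 | measured value; has little effect on the phase structure |
| `froude` | inertia/friction ratio | 0.1 | friction-dominated regime of real snakes and snake robots |
| `velocity_reg` | Coulomb regularization $\delta$ (BL/period) | 1e-6 | see numerics |

All defaults are materialized into every metadata sidecar the package
writes, so outputs are self-describing.

## Steady-state metrics

Behaviour is summarized over a late one-period window (default: the
final period of a 10-period run, released from rest with the wave
already imposed — transients decay within a couple of periods at
Fr = 0.1) by three quantities:

* **pose angle** $\gamma$: period average of
  $\mathrm{atan2}((\bar{\mathbf t}\times\bar{\mathbf u})\cdot e_z,\,
  \bar{\mathbf t}\cdot\bar{\mathbf u})$, the signed angle from the mean
  orientation to the travel direction;
* **steering rate** $\dot\theta$: net rotation of the travel heading
  per period;
* **effective speed** $|v_\mathrm{eff}|$: magnitude of the
  window-averaged COM velocity expressed in the frame co-rotating with
  the heading.

A design choice deserves emphasis: all three metrics are computed from
the *one-period trailing mean* of the COM velocity (equivalently, the
displacement over the preceding period) and of the mean orientation,
not from instantaneous values. At steady state the motion is periodic,
and the one-period moving average annihilates every intra-period
harmonic exactly, leaving the macroscopic drift. The instantaneous
realization is badly behaved precisely where the interesting physics
is: a snake that oscillates in place (isotropic friction, no lifting)
has an instantaneous velocity heading that winds through $2\pi$ every
period, and a naive co-rotating average returns the mean *speed* of the
wobble instead of the near-zero drift. With the period-smoothed
realization, a stationary oscillator measures $\sim 10^{-6}$, a
straight path returns its speed exactly, and a uniform circular path
returns the angular rate and — after the chord-to-arc correction
$(\beta/2)/\sin(\beta/2)$, with $\beta$ the rotation per period — the
exact tangential speed. These three constructed cases are frozen into
the unit tests. Angle averages unwrap their integrand first so
backward travel ($\gamma\approx\pi$) does not suffer branch-cut
artifacts.

Classification uses fixed, configurable bands (straight when
$|\dot\theta| < 0.05$ rad/period; slithering, sidewinding, backward for
$|\gamma|$ below 0.35, in [0.35, 2.6], above 2.6 rad; spinning when
$v_\mathrm{eff} < 0.02$ BL/period with $|\dot\theta| \ge 0.05$). The
cutoffs are not measurements — they are round numbers chosen to carve
the observed phase topology cleanly, and they ship in the output
metadata so downstream users can re-classify. Runs whose metrics have
not settled between the last two one-period windows are labelled
`transition`.

## Numerical choices

* **Arclength grid.** 201 uniform nodes with trapezoidal quadrature by
  default. $I[\cdot]$ is a cumulative trapezoid minus its quadrature
  mean, which makes the mean-zero property exact in floating point
  (the same rule is used for both), so reconstruction invariants hold
  to machine precision while smooth integrands converge at second
  order. Closed-form checks ($I[1] = s - 1/2$, straight-body
  $J = 1/12$) hold exactly or at quadrature order respectively.
* **Velocity regularization.** The Coulomb direction $v/|v|$ is
  replaced by $v/\sqrt{|v|^2+\delta^2}$ with $\delta = 10^{-6}$
  BL/period. Body-node speeds are $O(1\!-\!10)$, so the regularization
  is inert except at isolated zero crossings; reported metrics move by
  far less than $10^{-3}$ when $\delta$ is changed tenfold (tested).
* **Time integration.** deSolve's Dormand–Prince `ode45` at
  rtol 1e-8 / atol 1e-10, with the right-hand side compiled (Rcpp).
  The force density is continuous in time (the Heaviside split
  multiplies a factor that vanishes at the switch), so no event
  handling is needed. An independent R assembly of the same equations
  is kept as the reference implementation and cross-checked against
  the compiled path at 1e-12.
* **Problem sizes.** Single-run studies use the defaults above
  (~0.25 s per 10-period run). Parameter sweeps use 101 nodes and
  rtol 1e-6 (~0.1 s per cell), which moves metrics by well under the
  classifier bands; the shipped phase maps are 41 × 41, with
  resolution a flag. Label agreement between 21 × 21 and 41 × 41
  grids exceeds 90% on coincident cells (tested).
* **Separatrices.** Zero contours of $\dot\theta$ and $\gamma$ come
  from marching squares (`grDevices::contourLines`) with linear
  interpolation; when the level coincides with node values the contour
  is nudged by a small fraction of a cell, which is harmless at map
  resolution.

## Friction landscapes

Heterogeneity is a multiplicative scale on the whole friction
coefficient vector, evaluated at each node's instantaneous lab
position: disks (posts become high-friction patches), strips
(frictionless bands; scale 0 is allowed), linear radial gradients
(lens-like focusing/defocusing), and nearest-cell rasters. Where
primitives overlap, the **last listed wins** — a deterministic,
documented rule. Deflection ensembles are deterministic by design:
members differ only in their lateral launch offset (and optionally
entry phase), since the underlying dynamics have no randomness and the
spread of deflection angles comes from where the body meets the
pattern. The deflection angle is measured between the heading averaged
over one period before first contact with the pattern and one period
after the last contact (contact = any body node sampling a
non-background scale); snakes with negligible displacement over the
final two periods are flagged stuck and excluded from the binned pdf
but still counted.

## What the planar model does and does not capture

Passing tests demonstrate properties of the *planar effective-friction
idealization*, not of real snakes: the model has no substrate
remodeling or memory (sand flow, compaction), no true 3D contact or
body elasticity, no static friction, and solid obstacles are reduced to
high-friction patches rather than rigid walls. Quantitative agreement
with animal or 3D-simulation deflection statistics is therefore out of
scope here; the landscape module targets the nulls and symmetries that
the idealization must satisfy (uniform maps deflect nothing, mirrored
landscapes with mirrored gaits negate deflections, vanishing-width
strips do nothing).

## Known limitations and edge behaviour

* With the measured backward ratio $\mu_b/\mu_f = 1.5$, fore-aft
  symmetry is broken even at $\mu_t/\mu_f = 1$: the no-lift gait
  retains a small backward drift (~0.006 BL/period, converged under
  grid, tolerance, and regularization refinement), and the signed net
  speed crosses zero near $\mu_t/\mu_f \approx 1.025$ rather than
  exactly 1. At phase-map scale this reads as immobility.
* The curvature-tied lifting stereotype $\hat N = e^{-\kappa}$ (the
  normalization constant is irrelevant after weight renormalization,
  which is why none is stated) concentrates weight by a factor
  $e^{2\epsilon} \approx 10^6$ at $\epsilon = 7$ and behaves like an
  extreme one-sided gait; it is provided for comparison, not as a
  recommended template.
* The pose-angle separatrix bends away from $\Phi \in \{0, 1/2\}$ with
  increasing lifting amplitude (to $\Phi \approx 0.06$ at $|A| = 2$,
  $\mu_t/\mu_f = 2$); only the steering-rate separatrix hugs
  $\Phi \in \{1/4, 3/4\}$ to within a grid cell.
* `transition` labels conflate genuine slow convergence with cells
  whose simulation failed; the per-cell flag column distinguishes the
  two.

## Reproducibility

Everything the package computes is a pure function of its
configuration; identical configurations give byte-identical CSV
content. `scripts/acceptance.R` recomputes the headline quantities
(symmetry nulls, slithering rectilinearity/tangency, isotropic no-lift
speed, Froude bookkeeping) from scratch against the installed package.
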