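---
title: "Methods: bifurcation analysis of the forest-grassland mosaic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bifurcation analysis of the forest-grassland mosaic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mosaicbif)
```

This vignette documents the model, the numerical methods and the design
choices behind `mosaicbif`, at the level of detail a user needs to judge
what a computed diagram does and does not establish.

## The model and its assumptions

The state is $(f, x)$: the forest fraction of a mosaic landscape and the
fraction of people preferring forest. The coupled system is

$$\dot f = w(f)\,(1-f)\,f - \nu f - J(x), \qquad
  \dot x = s\,x(1-x)\,u(f),$$

with the fire-mediated recruitment switch
$w(f) = c\,/\,(1 + e^{-k f/(1-f) + b})$, the perceived-value function
$u(f) = r(1-f)^m - q f^n$ and the opinion feedback $J(x) = h(1-2x)$.
Grassland is the complement $g = 1 - f$. The assumptions baked into this
structure:

* fire suppresses recruitment in open landscapes and is itself
  suppressed by closed forest, hence the sharp sigmoid in the odds
  $f/(1-f)$; the switch is singular at $f = 1$, so all evaluations are
  guarded at $f \le 1 - 10^{-9}$;
* opinion follows a majority (replicator-type) rule weighted by
  scarcity: forest gains perceived value when rare;
* management acts additively on the landscape at rate $h$. Because
  $J$ is additive, trajectories started at extreme states (high $f$
  together with strong forest preference) can transiently leave the
  unit interval in $f$; integrators in this package carry a domain
  guard and flag such runs rather than continuing through the
  singularity.

Parameters and units (rates are per year; the time unit itself is a
labelling convention — reading rates per decade rescales all rate
parameters uniformly and changes no bifurcation structure):

| parameter | meaning | default |
|---|---|---|
| `b` | recruitment switch offset | 11 |
| `c` | recruitment ceiling (rate) | 1 |
| `k` | fire-activation steepness | swept |
| `nu` | natural forest→grassland conversion (rate) | swept |
| `s` | social learning rate | 10 |
| `h` | strength of human influence (rate) | 2 |
| `r, q, m, n` | perceived-value gains / exponents | 1, 1, 1, 1 |

The defaults are the baseline conditions of the analysis; `h = 2`
(strong interaction) is the value used for all bifurcation diagrams,
and the `(k, \nu)` window of interest is $k \in [0, 50]$,
$\nu \in [0, 3]$. The general $u(f)$ is implemented, but all closed
forms below require the default shape $u = 1 - 2f$ (the
`has_default_u()` predicate guards them).

## Equilibria and their continuation

With the default $u$, interior steady states satisfy $u(f) = 0$, i.e.
$f^* = 1/2$, and the forest balance then gives
$x^* = 1/2 + (\nu/2 - w(1/2)/4)/(2h)$ (`interior_equilibrium()`;
rejected when $x^* \notin (0,1)$). The Jacobian there has
$\partial \dot x/\partial x = 0$, so

$$\tau = w'(1/2)/4 - \nu, \qquad \Delta = 4 h s\, x^*(1 - x^*) > 0 .$$

The positive determinant means the interior equilibrium is never a
saddle: stability is lost only through the trace, i.e. through a Hopf
bifurcation. Equilibria on the invariant lines $x = 0, 1$ are found by a
sign scan of the one-dimensional balance on a $10^4$-point grid plus
bisection (`boundary_equilibria()`); they are reported but kept out of
the regime classification, which concerns the interior dynamics.

`continue_branch()` is a standard pseudo-arclength predictor–corrector
for $F(u, \alpha) = 0$: tangents from the null space of the extended
Jacobian (analytic in $u$, finite-difference in $\alpha$), a Newton
corrector in the tangent hyperplane at tolerance $10^{-6}$ (the solver
polishes two extra steps beyond acceptance, so branch points are
accurate to $\sim 10^{-10}$), arclength steps starting at 0.01 with
halving on failure and a ceiling of 0.1 (continuation settings are this
package's own; only the Newton tolerance is inherited from the study
conditions). Eigenvalues ride along each point; real parts below
$10^{-9}$ in magnitude are flagged `marginal` rather than forced into
stable/unstable, because Hopf points live exactly there.

## Hopf points, the first Lyapunov coefficient, Bautin points

On the interior family the zero-trace condition gives the closed-form
Hopf locus

$$\nu_H(k) = \frac{c\,k\,e^{b-k}}{(1 + e^{b-k})^2},$$

re-derived from the analytic Jacobian and cross-checked in the test
suite against eigenvalue-based detection along continued branches
(`detect_hopf()`, which brackets sign changes of the real part of the
complex pair and bisects the trace to $|\tau| < 10^{-9}$). The angular
frequency is $\omega = \sqrt\Delta = 2\sqrt{h s x^*(1-x^*)}$.

Criticality uses the standard planar normal-form reduction
(`first_lyapunov_coefficient()`): shift the equilibrium to the origin,
map the Jacobian to rotation form $[[0, -\omega], [\omega, 0]]$ through
the real and imaginary parts of the critical eigenvector, transform the
analytic second- and third-order derivative tensors (hand-derived
closed forms; finite differences are kept only as a test oracle,
because the sign of a third-order quantity near its zero is exactly
where numerical tensors are least trustworthy), and evaluate

$$16 a = f_{uuu} + f_{uvv} + g_{uuv} + g_{vvv}
 + \tfrac{1}{\omega}\!\left[f_{uv}(f_{uu} + f_{vv})
 - g_{uv}(g_{uu} + g_{vv}) - f_{uu} g_{uu} + f_{vv} g_{vv}\right].$$

Only the sign and zeros of $l_1 = a$ are meaningful; the normalization
is convention-dependent and no test asserts a magnitude. $l_1 < 0$ is
supercritical, $l_1 > 0$ subcritical, $|l_1| < 10^{-8}$ degenerate.

A useful structural fact falls out of the reduction: at $f^* = 1/2$ the
transformed quadratic terms cancel identically, so on the Hopf locus
$l_1 \propto \phi'''(1/2)$ with $\phi = w f (1-f)$, which reduces to
$k\,S'''(k-b) + 3 S''(k-b)$ for the logistic $S$. Its zeros — the
**Bautin points** — therefore depend only on $k$ and $b$, not on $c$,
$s$ or $h$ (those enter $\nu_{GH} = \nu_H(k_{GH})$ and $x^*_{GH}$).
`find_bautin()` does not use this shortcut: it brackets the sign change
of the numerically evaluated $l_1$ along the locus and refines by
Brent's method; the closed-form condition serves as an independent
oracle in the tests. For the baseline regime the two Bautin points come
out at $(k, \nu) = (9.9398, 1.8994)$ and $(12.5934, 1.7678)$; the
fold-of-cycles curves computed below terminate on these points to
within $1.5\times10^{-4}$, an independent confirmation by pure cycle
continuation. Between the two Bautin $k$ values the locus is
supercritical, outside subcritical, which is why $k$-sweeps at
$\nu \le 1.77$ show two subcritical Hopf points, sweeps at
$\nu \ge 1.90$ two supercritical ones, and sweeps in the narrow window
between show one of each.

## Limit cycles through a Poincaré return map

For a planar system a periodic orbit is a fixed point of the scalar
return map $P$ on a ray transverse to the flow. The ray is anchored at
the encircled focus — for the mosaic model the vertical line $f = 1/2$
through the interior equilibrium, crossed upwards in $f$ (at $f = 1/2$
the crossing speed is $2h(x - x^*)$, so transversality is automatic on
the upper ray). The map and its *exact* derivative are computed by
integrating the variational equations alongside the trajectory
(`lsodar`, absolute/relative tolerances $10^{-12}/10^{-10}$, with event
functions for the section crossing and the domain guard); the
derivative of $P$ at a fixed point is the nontrivial Floquet
multiplier.

This is a deliberate design choice over multiple shooting with a fixed
segment mesh: in the plane the periodic boundary-value problem is a
*scalar* root problem, the phase condition is the section itself
(anchored at the focus), discretization error is controlled by the
adaptive integrator rather than a segment count, and unstable cycles
pose no difficulty because Newton on $P(a) - a$ does not iterate the
flow map repeatedly. The closure tolerance is $10^{-8}$; the
convergence check in the tests recomputes a cycle at two integrator
tolerances and requires the period to agree to $10^{-6}$ relative.

* `initial_cycle_from_hopf()` chooses the cycle side from
  $\mathrm{sign}(l_1)$ and the trace derivative, displaces the
  parameter by a small offset (doubled up to three times on failure),
  brackets the nontrivial fixed point on a geometric ray grid, and
  polishes by Newton.
* `continue_cycle_branch()` is pseudo-arclength continuation in the
  (ray coordinate, parameter) plane with a trust region around each
  predictor, which keeps the corrector from leaping onto the two
  spurious fixed-point families of the map (the equilibrium itself, and
  degenerate orbits hugging the invariant line $x = 1$). The ray
  coordinate is allowed to cross zero: the section anchor is frozen at
  the seed parameters, and the orbit family may drift across it.
  Branches terminate on amplitude collapse (the Hopf end), period
  blow-up, a parameter range boundary, or step stall.
* `floquet_multipliers()` recomputes the monodromy matrix over one
  period; the trivial multiplier must be 1 within $10^{-4}$, and the
  product of the multipliers is cross-checked against the Liouville
  integral $\exp\int \mathrm{tr}\,J\,dt$.
* `detect_lpc()` locates folds where the parameter component of the
  branch tangent changes sign and refines each by a two-dimensional
  Newton solve of the exact fold system $\{P(a) = a,\ P'(a) = 1\}$ —
  tighter than bracket bisection; the multiplier condition
  $|P' - 1| < 10^{-3}$ holds by construction at the solution.
* `trace_lpc_curve()` continues the fold system in a second parameter,
  re-anchoring the section at the current interior equilibrium at each
  step and bisecting failed steps. Two guards reject the degenerate
  solution that sits on the Hopf locus with vanishing amplitude (it
  satisfies both fold equations): an absolute amplitude floor of
  $10^{-4}$ and a continuity requirement that the fold amplitude not
  collapse below a quarter of its previous value in one step.

Labelling convention: `H1` is always the smaller-$k$ Hopf point of a
sweep, `LPC1` the fold on the $k < b$ flank.

## The regime map

`classify_regime()` assembles the attractor inventory at one $(k, \nu)$
point: interior equilibrium stability plus a census of the return map
$P(a) - a$ over a ray grid (40 points by default, from $2\times10^{-3}$
above the focus to just inside the domain boundary), each sign change
converged by bracketed Newton. The labels are I (stable equilibrium, no
cycle), II (unstable equilibrium, one stable cycle), III (stable
equilibrium, unstable + stable cycle). The census resolution bounds the
smallest detectable cycle; at the mapped points the relevant cycles
have amplitudes two orders of magnitude above that floor. Points within
$10^{-3}$ (in $\nu$, or in $k$ against the fold curves) of a bounding
curve are labelled `boundary` rather than forced into a region.

`build_regime_map()` prefers the curve-based partition: the closed-form
Hopf bell, the two Bautin points, and the two LPC curves grown from a
seed slice (default $\nu = 0.2$) upward to their Bautin end points and
downward to the window edge. Region II is the area under the bell;
region III lies between an LPC curve and the bell on either flank,
below the respective Bautin $\nu$ — which is why no region-III sample
exists above the larger Bautin $\nu$, and why the bistability width
shrinks as $\nu$ grows. A grid verification against the direct
inventory classifier is available (`verify_n`).

## Simulation experiments

`integrate_model()` runs `lsoda` at tolerance $10^{-10}$ with the
domain guard as an event. `shift_experiment()` settles the system
before a perturbation at $t_p$ (default 100 years) and classifies the
transition. Two perturbation kinds, with deliberately different
operational criteria:

* **state kick**: catastrophic iff the asymptotic oscillation amplitude
  jumps by more than a factor 5 (with a floor of 0.02 on the reference
  amplitude) — i.e. the kick crossed the basin boundary. A zero kick is
  trivially smooth.
* **parameter step**: the post-step attractor generally differs from
  the pre-step one even for a smooth transition (crossing a
  supercritical Hopf point turns a steady state into a small
  oscillation), so the amplitude ratio alone cannot separate the two.
  The step is therefore additionally walked quasi-statically in 20
  increments, tracking the attractor amplitude; the shift is
  catastrophic iff that path contains a discontinuous jump (the same
  factor-5 criterion between consecutive increments). Across a
  subcritical Hopf or an LPC fold the amplitude jumps by an order of
  magnitude in one increment; across a supercritical Hopf it grows
  like $\sqrt{\delta}$ and never triggers.

Steady state is declared when the windowed amplitude varies by less
than $10^{-4}$ over 100 years, with a 2000-year cap (`undecided`
otherwise). `basin_membership()` decides between a stable equilibrium
and a stable cycle by trailing amplitude against each attractor; the
test suite confirms that the decision boundary is the computed unstable
cycle (points 3% inside/outside its mesh polygon classify
differently).

## Normal-form benchmarks

Every numerical stage is validated on two synthetic systems with fully
known answers, exposed through the same interface as the study model so
the pipeline code cannot special-case them:

* `hopf_normal_form(omega, cubic_sign)`: eigenvalues
  $\mu \pm i\omega$ at the origin, $l_1$ sign equal to `cubic_sign`,
  and (supercritical case) the exact cycle $r = \sqrt\mu$, period
  $2\pi/\omega$, nontrivial multiplier $e^{-2\mu T}$.
* `bautin_normal_form()`: radial dynamics
  $\dot r = \beta_1 r + \beta_2 r^3 - r^5$; Hopf line $\beta_1 = 0$,
  $l_1$ with the sign of $\beta_2$, Bautin point at the origin of the
  parameter plane, cycle radii from the radial quartic, and the LPC
  curve $\beta_1 = -\beta_2^2/4$.

These fixtures exercise the eigenplane transform, the $l_1$ sign, cycle
convergence, fold detection and two-parameter fold continuation against
closed forms (recovered in the tests to $10^{-6}$ or better, and
end-to-end to the $10^{-3}$ the pipeline guarantees). What they do not
emulate: the mosaic model's singular boundary at $f = 1$, its invariant
lines, slow–fast relaxation cycles far from onset, and the drift of the
encircled focus with the parameters — those paths are exercised on the
model itself in the test suite.

## Problem sizes and runtimes

The shipped tests run the full $\nu = 0.2$ cycle branch (about 200
accepted cycles across both folds), both LPC curves to their Bautin end
points, regime censuses at the reference points, and the complete
normal-form recovery, in roughly six minutes on one CPU. The regime-map
test uses a $\nu = 0.4$ seed slice (a shorter branch with the same
structure) and 8 + 10 fold steps per LPC curve; these sizes are the
package's default trade-off between resolution and turnaround, and all
of them are arguments, not constants.

## Known limitations

* Closed forms (interior equilibrium, Hopf locus, `find_bautin`)
  require the default perceived-value shape; for general $u$ the
  generic Newton/continuation route applies but the Bautin search must
  be assembled manually from `detect_hopf` over slices.
* The additive feedback lets extreme initial states leave $f \in [0,1)$
  in finite time; such runs are flagged, not continued.
* LPC coordinates away from the Bautin points have no closed-form
  cross-check in the model itself; their accuracy rests on the fold
  system's Newton tolerance and the integrator, validated on the
  Bautin normal form.
* No Bogdanov–Takens, cusp or homoclinic machinery: the interior family
  has $\Delta > 0$ identically, so those codimension-2 scenarios cannot
  arise on it and no fold-of-equilibria continuation is provided.
* Second Lyapunov coefficients are not computed; the fold-of-cycles
  branch near a Bautin point is obtained numerically instead of from
  the codimension-2 normal form.
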