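---
title: "Estimating muscle forces during gait: models, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating muscle forces during gait: models, criteria and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmuscle)
```

## The muscle redundancy problem

During walking, many more muscles cross each joint than are mechanically
necessary: in the model this package targets, 43 muscles of the right leg
actuate six degrees of freedom (three at the hip, knee flexion/extension,
ankle plantar/dorsiflexion and inversion/eversion). Net joint moments
obtained from inverse dynamics therefore under-determine the individual
muscle forces, and some model of how the central nervous system distributes
load is needed. The standard resolution is a constrained optimization solved
at each time frame:

$$\min_{\mathbf F} \; C(\mathbf F)
\quad \text{s.t.} \quad
\mathbf J^{\!\top}\mathbf F = \mathbf Q^{ID},
\qquad F_i^{Min} \le F_i \le F_i^{Max},$$

where the rows of $\mathbf J^{\!\top}$ are the per-frame moment arms, and
$\mathbf Q^{ID}$ the inverse-dynamics moments. The package implements four
recruitment costs $C$:

* **Criterion I** — $\sum_i F_i^2$ (squared forces),
* **Criterion II** — $\sum_i (F_i/F_{0,i}^M)^2$ (squared relative forces),
* **Criterion III** — $\sum_i (F_i/PCSA_i)^2$ (squared stresses),
* **Criterion IV** — $\min \max_i (F_i/F_{0,i}^M)$ (min/max; the largest
  relative force is made as small as possible).

The bound rules distinguish the methods being compared:

* **SO** (static optimization): constant bounds $[0, F_0^M]$; no muscle
  physiology in the constraints.
* **PHY1**: elastic tendon. The previous frame's state $(a, F)$ is
  extrapolated through the coupled activation + contraction dynamics with
  the excitation held at 0 and at 1, giving a reachable force corridor for
  the next frame.
* **PHY2**: rigid tendon, activation dynamics kept in its exact discrete
  form; bounds are the rigid-tendon forces at the one-step-reachable
  activation extremes.
* **PHY3**: rigid tendon, activation dynamics ignored ($a = u$); bounds are
  the rigid-tendon forces at $a = 0$ and $a = 1$.

All physiological variants use criterion I as the cost.

## Musculotendon model

Each actuator is a Hill-type model: contractile element (activation-scaled
active force-length and force-velocity curves) in parallel with a passive
elastic element, in series with a tendon, with pennation handled through a
constant inter-aponeurosis width $w = l_0^M \sin\alpha_0$. The exact
characteristic-curve formulas are a modelling choice, not something the
problem dictates; the package uses the standard smooth forms (Gaussian
active force-length, exponential passive force-length, hyperbolic concentric
force-velocity joined $C^1$-continuously to a saturating eccentric branch
with plateau 1.4, and an exponential-toe-then-linear tendon with 4% strain
at maximal isometric force). Every coefficient is an argument of
`hill_curves()` so alternative parameterisations can be swapped in. The
maximal contraction velocity, needed to normalize fiber velocities, is not
universal either; the default is 10 optimal fiber lengths per second,
standard in the musculotendon literature, and configurable.

Two deliberate choices deserve a note:

* The strict activation-scaled rigid-tendon form $F = a\,g(l^{MT}, v^{MT})$
  has no passive term. Since the model explicitly contains a parallel
  passive element, the package includes the passive force additively (not
  scaled by $a$) by default; `hill_curves(include_passive = FALSE)` gives
  the strict form.
* Under the rigid tendon, differentiating
  $l^M\cos\alpha = l^{MT} - l^T_s$ at constant $w$ gives the fiber velocity
  $v^M = v^{MT}\cos\alpha$, which is what `rigid_tendon_force()` uses.

### Subject-specific scaling

Length parameters are scaled in two steps: first $l_0^M$ and $l_s^T$ are
multiplied by the ratio of subject to generic musculotendon length in the
standing posture (`scale_length_params()`); then the optimal fiber length is
clamped to the maximum rigid-tendon fiber length over the motion
(`clamp_optimal_length()`), so the normalized fiber length peaks at exactly
1 and stays in the physiological window $(0.5, 1.2]$. Because $w$ itself
depends on $l_0^M$, the clamp is iterated to its fixed point (the update is
a contraction with rate $\sin^2\alpha_0 < 1$, so a handful of iterations
reach machine precision); afterwards both $w = l_0^M\sin\alpha_0$ and
$\max_t \bar l^M = 1$ hold exactly. Dips below 0.5 raise a warning rather
than an error, since the clamp rule itself cannot prevent them.

### Activation dynamics

First-order dynamics $\dot a = (u - a)/\tau$ with $\tau = \tau_{act} =$
15 ms while activating ($a \le u$) and $\tau_{deact} =$ 50 ms while
deactivating. With constant excitation over a step the exact solution is the
exponential update implemented by `activation_step()`; the branch is chosen
from $a(t_{k-1})$ versus $u(t_k)$, and a tie is a fixed point, so the
choice there is immaterial.

### Elastic-tendon integration

The PHY1 corridor requires integrating the coupled system over each 10 ms
frame step, twice per muscle. The series-elastic tendon makes this stiff, so
`contract_integrate()` uses an A-stable implicit trapezoidal scheme: the
activation sub-state is advanced by its exact exponential solution and only
the scalar force state is solved implicitly (damped Newton on the stage
equation), on 10 substeps by default, with kinematics interpolated linearly
within the step. The tests verify this integrator against a stiff
general-purpose ODE solver.

Two numerical points:

* At exactly zero tendon strain the nominal tendon stiffness is zero, which
  would make $F = 0$ an absorbing state — a silent muscle could never
  produce force again. Inside the contraction dynamics the toe-region
  right-limit stiffness is therefore extended below slack (the tendon
  force-strain *curve* still returns 0 below slack); the force state may
  dip marginally below zero and is clamped at use.
* When the force balance requests a force-velocity value outside the
  curve's range (e.g. near-zero active capacity), the query is clamped to
  the curve domain and the fiber velocity to $\pm v_{max}$. When there is
  neither drive nor load, the fiber velocity is taken as zero rather than
  maximal shortening: the state is indeterminate and the neutral choice
  keeps the dynamics quiescent.

## Solving a trial

`solve_frame()` solves one frame. Polynomial criteria are strictly convex
and separable, so the solver works on the dual: the primal forces are a
clamp of a closed-form function of $\mathbf J\lambda$, and a damped
semismooth Newton iteration (initialized at the unconstrained-interior dual
solution) drives the equality residual below $10^{-6}$ relative — usually in
a handful of iterations, finitely for quadratic costs. Criterion IV is
solved through its linear-programming reformulation (auxiliary level
variable, solved with the classical simplex method). Because the min/max
optimum generally fixes only the bottleneck muscles, a lexicographic
tie-break then minimizes $\sum (F_i/F_{0,i}^M)^2$ subject to the optimal
level, making the reported solution unique and reproducible; this tie-break
is a package choice beyond the comparison framework itself.

`solve_trial()` runs a gait cycle: frame 0 starts from the best of five
seeded population-based global searches (population 50, a compact
real-coded evolutionary scheme) refined by the frame solver — mirroring the
protocol of multi-start global seeding before gradient refinement — and
every later frame is warm-started from the previous optimum. Since the
per-frame problems are convex, the global seeding fixes the protocol path
rather than the optimum; it matters only as provenance of the initial
guess. For the physiological methods the per-muscle state propagates
sequentially; for PHY1 the activation consistent with the solved force is
recovered by root-finding the constant excitation whose one-step
integration reaches that force.

Infeasible frames (bounds that cannot reproduce the moment) abort the run
by default, reporting the minimal constraint violation found by a phase-1
feasibility LP; a soft fallback (`protocol = list(soft = TRUE)`) keeps the
minimal-violation point and flags the frame instead.

## Synergy optimization

`solve_syno()` abandons per-frame equality constraints and instead optimizes
all frames at once over a low-dimensional control space: activations are
$a^* = B\,N\,V$ with $B$ a clamped cubic B-spline basis ($p = (f-1)/5 + 1$
nodes, rounded half away from zero), $N$ the non-negative nodal values and
$V$ the non-negative synergy vectors, each row summing to 1. The cost is

$$\beta \sum_{j,k}
\left[\frac{Q^{MT}_{jk} - Q^{ID}_{jk}}{\max_j |Q^{ID}_k|}\right]^2
+ \sum_{i,j}\left(a^{*2}_{ij} + \lambda_{ij} (a^*_{ij}-1)^2\right),$$

with $\beta = 100$, $\lambda_{ij} = 10^5$ outside $[0,1]$ and zero inside,
and forces mapped from activations by the same rigid-tendon model PHY3
uses. The spline degree is a package choice (cubic, clamped uniform knots —
the conventional choice for smooth activation trajectories; configurable).
The sum-to-one simplex constraint is enforced by a softmax
reparameterisation inside L-BFGS-B (nodes are box-bounded at zero), which
satisfies the constraints exactly at the returned point; gradients are
analytic (the tracking term is quadratic in $a^*$, and $a^*$ is bilinear in
the design variables). Five seeded random restarts are run and the best
kept; nodes start uniform in $[0, 0.5]$ and vectors as normalized symmetric
random weights.

Moment agreement is summarized as
$100\,(1 - \mathrm{RMS}(Q^{MT}_k - Q^{ID}_k)/\mathrm{RMS}(Q^{ID}_k))$
averaged over the six degrees of freedom (`moment_matching()`). The metric
behind published "matching percentage" figures is rarely spelled out; this
definition is the package's own, documented and configurable through the
function's `by_dof` argument.

## EMG validation

Estimated activations are compared against EMG envelopes by shape:
`envelope()` rectifies, low-pass filters (zero-phase 5th-order Butterworth,
6 Hz — fully specified, hence the canonical path) and normalizes to unit
peak; a singular-spectrum-analysis mode (window 250 samples, components
kept by eigenvalue share) is provided as the alternate smoother, the two
being practically equivalent on gait EMG. `xcorr_pearson()` evaluates the
Pearson correlation at every integer-sample delay within ±150 ms and keeps
the maximum (ties broken toward zero delay); maximizing over the delay is
assumed since a fixed physiological delay is not identifiable from the
comparison alone. Activations at the trial rate are upsampled to the EMG
rate by spline interpolation before correlating. Method pairs are compared
by two-sided paired t-tests on per-subject mean correlations, reported raw
(uncorrected), with a correction option off by default to mirror the usual
presentation of such tables.

## The synthetic cohort

Subject gait data of the kind this pipeline consumes are rarely public, so
the package ships a generator (`gen_cohort()`) whose defaults are the study
conditions: ten subjects, 43 muscles, six DOFs, one 1.0 s gait cycle
sampled at 100 Hz (101 frames), EMG-like signals at 1 kHz from nine
channels. Its central design choice: **moments are derived from forces,
never the reverse**, so the moment equality constraints are feasible by
construction.

* Muscle parameters are drawn in physiological lower-limb ranges (F0M
  100–3000 N, optimal fiber lengths 5–15 cm, slack lengths 5–45 cm,
  pennation up to 0.35 rad).
* Musculotendon lengths are sums of one to three cycle-frequency harmonics
  around the neutral length, amplitude-bounded so the fiber segment stays
  positive; velocities are analytic derivatives. Moment arms are smooth,
  sign-constant, bounded by 8 cm, with every DOF actuated by agonists and
  antagonists at every frame.
* `least_norm` mode draws smooth moments by pushing a moderate-effort
  activation pattern (mean levels 0.05–0.25 with 80% modulation — walking,
  not maximal effort) through the moment arms, then emits the criterion-I
  optimum as ground truth, so the SO-I solve recovers it exactly. The
  moderate effort level is the generator's realism condition; it also means
  the moments are producible within one-step physiological force corridors,
  which real gait moments satisfy by construction but arbitrarily strenuous
  synthetic moments need not.
* `synergy` mode builds a rank-3 activation matrix from smooth periodic
  synergy bumps and Dirichlet-like weight rows, scaled to peak at 0.8, and
  maps it through the rigid-tendon model.
* EMG channels amplitude-modulate band-limited (20–450 Hz) Gaussian carrier
  noise with the upsampled activation, plus white measurement noise. This
  reproduces the rectify-filter-normalize processing chain faithfully; it
  does not emulate motor-unit physiology, crosstalk, or electrode artifacts,
  so high validation correlations on synthetic cohorts demonstrate pipeline
  correctness, not clinical fidelity.

The elastic-tendon method is exercised at a reduced desk scale (8 muscles,
3 DOFs) in the packaged checks; its cost is dominated by the two
integrations per muscle and frame, exactly the burden that motivates the
rigid-tendon simplifications.

## Known limitations

* Hill curve coefficients and the force-to-activation maps are assumptions;
  results on real data would inherit them.
* The min/max tie-break, the moment-matching metric, and the SSA component
  grouping rule are package choices where the field's conventions are
  under-specified; all are documented above and configurable.
* No muscle wrapping or path geometry: moment arms and musculotendon
  kinematics are inputs.
* The comparison tables on synthetic cohorts say nothing about which
  recruitment criterion best matches human EMG — that question needs real
  subjects; the synthetic cohort validates the machinery.
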