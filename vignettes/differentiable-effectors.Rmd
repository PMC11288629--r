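---
title: "Differentiable biomechanical effectors: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiable biomechanical effectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffeffector)
```

## The problem

Neural-network models of motor control need a body. A policy network that
emits muscle commands must act on a simulated musculoskeletal plant, read
back delayed and noisy sensory consequences, and be *trainable* through
that whole loop. The usual obstacle is that biomechanical simulators are
not differentiable, which forces slow reinforcement-learning algorithms.
This package implements the alternative: planar effectors whose every
stage — activation dynamics, muscle-path geometry, force generation,
rigid-body dynamics, integration — is written on a reverse-mode autodiff
tape, so a recurrent policy can be optimized by plain gradient descent
through the physics (backpropagation through time, through the body).

Two standard effectors are provided:

* **`ReluPointMass24`** — a 1-kg planar point-mass in a `[-1, 1]` m
  square, pulled by four linear muscles (maximum isometric force 500 N)
  anchored in an 'X' at the corners `(±2, ±2)` m. Muscle force is a
  clamped-linear function of activation; there is no length or velocity
  dependence, hence no intrinsic geometry beyond the pulling directions.
* **`RigidTendonArm26`** — a two-joint planar arm (shoulder, elbow; no
  gravity) driven by six rigid-tendon Hill-type muscles: mono-articular
  shoulder and elbow flexor/extensor pairs plus a bi-articular pair.
  Segment masses, centre-of-gravity offsets, inertias and lengths are the
  standard human-arm values (upper arm 1.82 kg / 0.309 m, forearm
  1.43 kg / 0.333 m).

## Model components and their assumptions

### Skeletons

The arm follows the textbook planar two-link form
`M(q) q̈ + c(q, q̇) + B q̇ = τ` with the inertia matrix's `cos(q₂)`
coupling and the Coriolis/centripetal vector; the plane is horizontal, so
there is no gravity term. The source formalization is cited rather than
printed in the literature this package follows; the form used here is the
unique rigid-body model determined by the published parameter set, and
the test suite checks it against an independent energy-based Lagrangian
derivation (finite differences of the kinetic energy) at 64 random
states to 1e-8 relative tolerance.

The joint viscosity matrix `B` defaults to **zero** because no value is
published for the configuration we reproduce; it is exposed as a
configurable 2×2 matrix (`two_link_params(viscosity=)`). Joint limits are
likewise not printed; defaults are shoulder `[0°, 135°]` and elbow
`[0°, 155°]`, configurable. On violation the position is clamped and the
outward velocity component zeroed. Angles are radians internally; degrees
appear only at configuration boundaries.

### Muscles

Excitation-to-activation dynamics is first order,
`da/dt = (u − a)/τ`, with `τ = 15 ms` when the (clipped) excitation
exceeds activation and `50 ms` otherwise — the young-adult constants of
the standard Hill formalization. The full published form makes the time
constants activation-dependent; the constant-τ variant is used because it
is first-order with the same asymmetry and admits a closed-form solution
that the test suite verifies directly. Actions outside `[0, 1]` are
clipped before the ODE.

The rigid-tendon Hill muscle produces
`f = fmax (a·FL(l̃)·FV(ṽ) + FP(l̃))` with

* `FL(l̃) = exp(−(l̃−1)²/0.45)` — Gaussian active force-length curve,
  maximal at the optimal fiber length;
* `FV` — hyperbolic concentric branch (zero force at the maximum
  shortening velocity of 10 optimal lengths/s, shape factor 0.25) and a
  saturating eccentric branch with plateau 1.4;
* `FP` — exponential passive curve (shape 4, strain scale 0.6) anchored
  at a configurable normalized **slack length, default 1.4**.

The slack-length default deserves a note. Anchoring the passive curve at
the optimal length (slack 1) — the textbook convention — is inconsistent
with the published arm geometry we reproduce: with the published length
polynomials the shoulder extensor sits near normalized length 1.44 at
the *centre* of the joint space, and a slack of 1 would produce roughly a
third of its maximal force passively at rest, contradicting the
passive-drift behaviour this class of models exhibits (quiet centre,
drift near the joint-space edges). Slack length is explicitly a modelling
choice in this family of simulators; 1.4 reproduces the expected drift
structure and is user-overridable (`muscle_params(normalized_slack_length=)`).

Under the rigid-tendon assumption the fiber length is the musculotendon
path length minus a constant tendon length. Two printed parameter values
required correction, documented here as deliberate deviations: the
elbow-flexor tendon length is taken as 0.172 m (not 0.0172 m, which
would leave that muscle 2.2–2.9× overstretched across the entire elbow
range), and the bi-articular flexor's shoulder coefficient as
−0.03 m/rad (not −0.3, which would make the musculotendon length
negative beyond ~63° shoulder flexion). Both corrected values match the
magnitude pattern of the neighbouring entries and the source
biomechanical model.

### Geometry and moment arms

A muscle path is an ordered list of fixation points in bone-relative
frames (body 0 = world). Path length is the summed straight-segment
length; there are no wrapping surfaces or conditional via points. The
moment arm with respect to a generalized coordinate is the partial
derivative of path length in that coordinate — positive when the muscle
lengthens as the coordinate grows — computed analytically from the
rigid-rotation derivatives of the fixation points and checked against
central finite differences (256 random states, absolute tolerance 1e-6).
Muscle force maps to generalized force as `τ = −MAᵀ f`: a pulling muscle
drives each coordinate toward shorter length.

For the training studies the arm's musculotendon lengths are the
published quadratic polynomials in the joint angles
(`len = a0 + a1s·θs + a1e·θe + a2e·θe²`), whose exact derivatives give
the moment arms; mono-articular muscles have exactly zero moment arm at
the unspanned joint. Muscle (path) velocity is the chain rule through
the geometry, `l̇ = Σⱼ MAⱼ q̇ⱼ`.

### Effector step

One 10-ms Euler step performs: activation ODE → geometry at the current
configuration → muscle force → generalized forces (muscle torques plus
the Jacobian-transpose image of any external endpoint force) → forward
dynamics → velocity update, then position update with the *new* velocity
(semi-implicit ordering, chosen for stability at this step size; the
cycle in the source architecture does not prescribe an order) → refresh
of the cartesian/muscle records at the new configuration. Resting
activation at reset is 0 for ReLU muscles and 1e-3 for Hill muscles — a
strictly numerical choice that avoids a dead multiplicative gradient at
exactly zero activation.

### Environments

Observations concatenate, in a fixed documented order: the 5 task inputs
(start x, y; target-input x, y; go-cue channel), 2 visual channels
(endpoint position delayed 50 ms plus Gaussian noise), and 2m
proprioceptive channels (muscle lengths and velocities, delayed 20 ms,
normalized by optimal muscle length — the literature does not state the
normalization; this scale-free reading is flagged as an interpretation).
Before a delay has elapsed the buffers return the reset state. The
go-cue is visual: the loss's desired position switches at the go-cue
instant, but the network's target-input and go-cue channels switch only
a visual delay later. Catch trials (half of training trials) never
deliver the go-cue, making the task postural. Observation noise is
resampled independently per element and step. The environment's reward
is identically 0 — learning uses the differentiable loss; the reward
slot exists for step-contract compatibility.

External forces compose a 100-ms mechanical perturbation (magnitude
U(0, 4) N, or U(0, 8) N on catch trials, random orientation and onset)
and/or the curl field `f = b(−ẏ, ẋ)` with `b = 8` N·s/m in the
adaptation study — always orthogonal to the endpoint velocity, hence
power-free.

### Policy and loss

The policy is one GRU layer (sigmoid gates, tanh candidate) plus a
sigmoid output node per muscle. Initialization: Glorot-uniform input
kernel, orthogonal recurrent blocks, zero biases, output kernel
N(0, 0.003²), output bias −5 — so initial actions are
`sigmoid(−5) ≈ 0.0067` and the effector starts quiet.

The loss is the time-mean of
`α·Lp + β·Lm + γ·Lh` plus `λ‖W‖`, with `α = 2, β = 5, γ = 0.1`:

* `Lp` — 0 inside the target radius (`r = 0.01` m; `r = 0` in the PMD
  study), otherwise the L1 distance to the desired position;
* `Lm` — muscle activation cost scaled by strength. The printed
  expression is typeset ambiguously; the default reading is
  `((uᵀf)/‖f‖₂²)²` with the alternative `Σ(u·f)²/‖f‖₂²` available as a
  configuration switch (`loss_config(muscle_loss_form=)`);
* `Lh` — `hᵀh/n + κ·ḣᵀḣ/n` with `κ = 0.05`; `ḣ` is the per-step hidden
  difference, not divided by dt (κ absorbs the constant; a dt-scaled
  variant only rescales κ);
* `λ = 1e-5` (the printed `10e-6` read literally) times the Frobenius
  norm of the GRU *input* kernel — "kernel weight matrix" in the
  singular is read as the input kernel, flagged as an interpretation.

Training is Adam with global gradient-norm clipping at 1.0. The
optimizer, learning rate and clip are nowhere specified in the source
material; they are community defaults and all configurable — the
acceptance checks are trend- and threshold-based so as to be robust to
this choice.

## The autodiff engine and the fused kernels

No autodiff library exists in this R environment, and the
differentiable-effector loop *is* the point of the package, so it ships
a small reverse-mode tape (`ad_begin()`, `ad_var()`, `ad_backward()`)
over batched matrices. Model code is written once against generic
operations (`v_mm`, `v_clamp`, ...) and runs identically on plain
numerics (fast simulation) or tape nodes (training).

Recording every elementary operation of an 80-step batched rollout costs
tens of thousands of tape nodes, which dominates runtime in R. The hot
path therefore uses *fused kernels*: one tape node per GRU step and one
per effector step, each with a hand-derived vector-Jacobian product, and
the loss is evaluated once on time-stacked records. The fused route is
an implementation detail, not a second model: piecewise masks use the
same strict inequalities as the elementary ops, and the test suite
asserts exact (1e-12) agreement of values *and* gradients between the
fused and elementary routes on both effectors, with noise, perturbations
and the curl field active, and checks both against finite differences.

Subgradient conventions at kinks (clamp boundaries, the force-velocity
branch point, the positional-loss radius) take the zero branch; these
events have measure zero along training trajectories.

## What the synthetic world does and does not establish

All data in this package are generated by its own simulator: the
"world" is the stated one — uniform starts and targets over the joint
box, uniform go-cues, 50% catch trials, the published delay (20/50 ms)
and noise (σu = 1e-2, σh = 1e-3 where stated) values, 10-ms Euler steps.
A green test therefore establishes internal correctness and the
reproduction of *structural* phenomena (adaptation, after-effects,
passive drift, PMD bias), not agreement with primate kinematics or
muscle recordings: there is no tendon compliance, no pennation, no
collision physics, no 3-D geometry, and straight-line muscle paths only.

Training-based checks run scaled down. The published studies use
7,680–38,400 batches (up to size 1024); the automated suite trains
hundreds of batches of 32–64 so the whole run fits a CI budget, and the
protocols expose `scale = "full"` for the published counts. A scaled run
shows the qualitative effects (loss descent, reach acquisition, curl
adaptation and after-effect, PMD bias); effect sizes at full scale are
larger and cleaner. Two caveats are worth naming: after ~2000 scaled
batches the reach endpoints straddle the 1-cm target radius (roughly
0.5–1.6 cm, seed-dependent) instead of settling safely inside it, and
the axis of the arm's PMD concentration has not yet converged to its
full-scale location even though the concentration itself is already
highly significant. The reduced sizes are declared in the protocols and
tests, chosen once for budget reasons — never tuned against the
acceptance thresholds.

## Numerical choices, degenerate inputs, known limitations

* Fiber lengths are floored at 0.01 optimal lengths inside the effector
  step: at extreme flexion the published bi-articular-flexor polynomial
  dips below the tendon length, and the floor keeps the force law
  defined (the standalone fiber-state operation instead raises an error,
  as its contract requires).
* The 2×2 inertia solve is done in closed form per batch row; the
  determinant is strictly positive for any positive parameter set.
* Euler at 10 ms is first order; the suite checks that halving the step
  halves the kinetic-energy drift of the free arm.
* Delays must be integer multiples of the timestep.
* The PMD protocol's literature source prints both "eight reaches" and
  "24 targets"; 24 targets (15° spacing) are used, matching its figures,
  with one trajectory per target. Its target radius is 0 there, 0.01 m
  elsewhere; both are honoured per-protocol.
* Whether activation integrates with the same dt as the skeleton is
  unstated; a single shared dt is assumed throughout.
* Ties in the PMD argmax break toward the lowest direction index.

## Reproducibility

Every stochastic component draws from R's global RNG; protocols and
training take explicit seeds, and identical (config, seed) pairs
reproduce results bit-for-bit — the suite asserts this for rollouts,
training runs and full protocols.
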