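# diffeffector

Differentiable biomechanical effectors controlled by recurrent neural
network policies, in pure R.

## Who this is for

Computational motor-neuroscience work that trains artificial neural
networks to control simulated bodies: the policy network must drive a
musculoskeletal plant, receive delayed noisy sensory feedback, and be
optimized by gradient descent *through* the body rather than by
reinforcement learning. This package provides that loop end-to-end —
plant, environment, policy, loss, trainer — with every stage recorded on
a built-in reverse-mode autodiff tape.

## What is inside

**Effectors.** A planar point-mass (mass `m = 1` kg, `ẍ = f/m`) pulled
by four linear ("ReLU") muscles in an X configuration
(`f(a) = fmax·clamp(a, 0, 1)`, `fmax = 500` N), and a two-joint,
six-muscle planar arm with rigid-tendon Hill-type muscles

```
f = fmax · ( a · FL(l̃) · FV(ṽ) + FP(l̃) )
```

with a Gaussian active force–length curve `FL`, a hyperbolic
force–velocity curve `FV`, an exponential passive curve `FP` beyond the
slack length, and first-order excitation→activation dynamics
`da/dt = (u − a)/τ` (τ = 15 ms activating, 50 ms deactivating). Moment
arms come either from declared muscle paths (`MA_j = ∂ℓ/∂q_j`,
analytically, checked against finite differences) or from the standard
quadratic length polynomials in the joint angles. Arm dynamics are the
planar two-link equations `M(q)q̈ + c(q, q̇) + Bq̇ = τ` (no gravity),
integrated by explicit Euler at dt = 10 ms.

**Environments** follow the standard `reset()`/`step(action)` contract:
observation = (start, target-input, go-cue) ++ visual endpoint feedback
(Δv = 50 ms delay) ++ proprioceptive muscle lengths/velocities
(Δp = 20 ms), each with optional Gaussian noise; 50% catch trials;
optional 100-ms mechanical perturbations and the velocity-dependent curl
field `f = b·(−ẏ, ẋ)`.

**Policy and training.** A one-layer GRU with sigmoid output nodes
(one per muscle), trained by backpropagation through time *and* through
the effector on the composite loss

```
L = mean_t( α·L_position + β·L_muscle + γ·L_hidden ) + λ‖W‖
    α = 2, β = 5, γ = 0.1, κ = 0.05, λ = 1e-5, target radius r = 1 cm
```

**Replication protocols**: curl-field adaptation with after-effects,
perturbation generalization (reaching + postural), preferential-movement
-direction (PMD) analysis over 24 reach directions, and the passive-drift
map. All are deterministic given `(config, seed)`.

## Worked example

```r
library(diffeffector)

arm <- RigidTendonArm26("paths")                       # path-based moment arms
st  <- effector_reset(arm, joint_position = c(45, 90) * pi / 180)
ad_value(st$cart$pos)
#> -0.017 0.454            # endpoint (m) at the standard test posture

geometric_moment_arms(arm$paths$EE, st, arm$P)
#>      dof1      dof2
#>         0    0.0379   # elbow extensor: no shoulder leverage, +3.8 cm elbow

drift <- passive_drift_map(grid_n = 21, duration = 0.2)
drift$drift[11, 11]; max(drift$drift)
#> 0                       # no passive force at the centre of joint space
#> 0.0386                  # up to ~3.9 cm drift in 200 ms near the edges

curl_field_force(c(1, 0), b = 8)
#> 0 8                     # curl field: 8 N, orthogonal to the velocity
```

Training a reach policy (scaled; the full published schedules sit behind
`scale = "full"`):

```r
eff <- RigidTendonArm26()
env <- RandomReach(eff, horizon = 0.8)
pc  <- policy_config(50, env$obs_size, eff$n_muscles)
pp  <- init_policy(pc, seed = 1)
fit <- train(env, pp, pc, loss_config(), batches = 1000, batch_size = 32,
             lr = 3e-3, seed = 2)        # ~6 min on one CPU
```

after which an 8-target centre-out test (`CentreOutReach`, 1-s window)
ends its reaches within 1–2 cm of the targets at under ~4 cm/s — see
`tests/testthat/test-acceptance.R` for the exact protocol and
thresholds, and `run_curl_field_protocol()` / `run_pmd_protocol()` for
the replication studies.

## Command line

A thin CLI lives at `inst/cli/diffeffector.R`:

```sh
Rscript inst/cli/diffeffector.R moment-arms --effector arm26 --grid 21 --out ma.csv
Rscript inst/cli/diffeffector.R muscle-curves --muscle EF --out curves.csv
Rscript inst/cli/diffeffector.R train --config train.json --seed 1 --out ckpt/
Rscript inst/cli/diffeffector.R experiment curl --scale ci --seed 1 --out out/
```

## Documentation

The methods vignette (`vignettes/differentiable-effectors.Rmd`) explains
the model assumptions, the parameter corrections, the autodiff engine
and its fused kernels, the scaled-down testing policy, and known
limitations (no tendon compliance, no collision physics, straight-line
muscle paths, planar only).
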