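#' @title Muscle actuators: linear piecewise (ReLU) and rigid-tendon Hill-type
#'
#' @description
#' Two phenomenological actuators drive the skeletons:
#'
#' * **ReLU muscle** -- force is a linear piecewise function of activation,
#'   `f(a) = fmax * clamp(a, 0, 1)`; no length or velocity dependence.
#' * **Rigid-tendon Hill-type muscle** -- force is
#'   `fmax * (a * FL(lnorm) * FV(vnorm) + FP(lnorm))` with a Gaussian active
#'   force-length curve, a hyperbolic force-velocity curve, and an
#'   exponential passive-stretch curve anchored at a configurable
#'   normalized slack length. Under the rigid-tendon assumption the fiber
#'   length is the musculotendon length minus a constant tendon length.
#'
#' Both muscle types share first-order excitation-to-activation dynamics
#' with distinct activation and deactivation time constants.
#'
#' Curve constants default to the published young-adult values of the
#' standard Hill formalization: activation/deactivation time constants
#' 15/50 ms, force-length width 0.45, force-velocity shape 0.25 with
#' eccentric plateau 1.4, maximum shortening velocity 10 optimal lengths/s,
#' passive exponential shape 4 with strain scale 0.6. The passive curve's
#' slack is at normalized length 1.4 by default (slack length is a
#' modelling choice; see the methods vignette for why the default is above
#' optimal length).
#'
#' @name muscle_models
NULL

#' Hill-type muscle parameters
#'
#' @param max_isometric_force fmax (N)
#' @param tendon_length constant tendon (series-element) length (m)
#' @param optimal_muscle_length fiber length at peak active force (m)
#' @param normalized_slack_length passive-curve slack, in optimal-length
#'   units; passive force is zero at or below it
#' @param tau_act,tau_deact activation/deactivation time constants (s)
#' @param fl_width Gaussian force-length shape factor
#' @param fv_af force-velocity shape factor
#' @param fv_flen eccentric force plateau (multiple of isometric force)
#' @param vmax maximum shortening velocity (optimal lengths / s)
#' @param pe_shape,pe_strain passive exponential shape and strain scale
#' @return object of class `muscle_params`
#' @export
muscle_params <- function(max_isometric_force,
                          tendon_length = 0,
                          optimal_muscle_length = 0.1,
                          normalized_slack_length = 1.4,
                          tau_act = 0.015, tau_deact = 0.05,
                          fl_width = 0.45,
                          fv_af = 0.25, fv_flen = 1.4, vmax = 10,
                          pe_shape = 4, pe_strain = 0.6) {
  stopifnot(max_isometric_force > 0, tendon_length >= 0,
            optimal_muscle_length > 0, tau_act > 0, tau_deact > 0, vmax > 0)
  structure(as.list(environment()), class = "muscle_params")
}

#' Linear piecewise (ReLU) muscle force
#'
#' `0` for `a <= 0`, `fmax * a` for `0 < a < 1`, `fmax` for `a >= 1`.
#' Total on the reals; exact piecewise (no smoothing), autodiff passes
#' subgradients at the kinks.
#'
#' @param activation activation(s), any shape (matrix or `advar`)
#' @param fmax maximum isometric force (N), scalar or broadcastable
#' @return force (N), same shape as `activation`
#' @export
relu_force <- function(activation, fmax = 500) {
  stopifnot(all(fmax > 0))
  fmax * v_clamp(activation, 0, 1)
}

#' Excitation-to-activation first-order dynamics
#'
#' `da/dt = (u - a) / tau`, with `tau = tau_act` while excitation exceeds
#' activation and the slower `tau_deact` otherwise. Excitation is clipped
#' to `[0, 1]` first.
#'
#' @param excitation u, matrix or `advar`
#' @param activation a, same shape
#' @param tau_act,tau_deact time constants (s)
#' @return da/dt (1/s)
#' @export
activation_derivative <- function(excitation, activation,
                                  tau_act = 0.015, tau_deact = 0.05) {
  u <- v_clamp(excitation, 0, 1)
  rising <- (ad_value(u) > ad_value(activation)) * 1
  tau <- rising * tau_act + (1 - rising) * tau_deact
  (u - activation) / tau
}

#' Rigid-tendon fiber state
#'
#' Under an inextensible tendon, fiber length = musculotendon length minus
#' tendon length, and fiber velocity = musculotendon velocity. Both are
#' returned normalized: length by the optimal muscle length, velocity by
#' `vmax * optimal_muscle_length` (so velocity is in maximum-shortening-
#' velocity units; shortening is negative).
#'
#' @param musculotendon_length total path length (m)
#' @param musculotendon_velocity its time derivative (m/s)
#' @param params [muscle_params()]
#' @return list with `len` (normalized fiber length) and `vel`
#'   (normalized fiber velocity)
#' @export
rigid_tendon_fiber_state <- function(musculotendon_length,
                                     musculotendon_velocity,
                                     params) {
  lv <- ad_value(musculotendon_length)
  if (any(lv <= params$tendon_length))
    stop("degenerate geometry: musculotendon length <= tendon length",
         call. = FALSE)
  len <- (musculotendon_length - params$tendon_length) /
    params$optimal_muscle_length
  vel <- musculotendon_velocity / (params$vmax * params$optimal_muscle_length)
  list(len = len, vel = vel)
}

# active force-length: Gaussian peaked at lnorm = 1
.fl_curve <- function(lnorm, width) exp(-((lnorm - 1)^2) / width)

# force-velocity: hyperbolic concentric branch, saturating eccentric branch
# vnorm in vmax units (shortening negative); FV(0) = 1, FV(-1) = 0,
# FV(+inf) -> flen
.fv_curve <- function(vnorm, af, flen) {
  # each branch is evaluated on its own clamped domain so the inactive
  # branch can never produce NaN/Inf that would poison the masked select
  vc <- v_clamp(vnorm, -1, 0)
  ve <- v_clamp(vnorm, 0, Inf)
  conc <- (1 + vc) / (1 - vc / af)
  c_ecc <- 2 + 2 / af
  ecc <- (flen * ve * c_ecc + (flen - 1)) / (ve * c_ecc + (flen - 1))
  shortening <- (ad_value(vnorm) <= 0) * 1
  v_clamp(v_where(shortening, conc, ecc), 0, flen)
}

# passive stretch: exponential in strain beyond the slack length, zero below
.fp_curve <- function(lnorm, slack, shape, strain) {
  s <- v_clamp(lnorm - slack, 0, Inf) / strain
  (exp(shape * s) - 1) / (exp(shape) - 1)
}

#' Hill-type muscle force (rigid tendon)
#'
#' `force = fmax * (a * FL(len) * FV(vel) + FP(len))`; all three curve
#' factors are nonnegative, FL peaks (=1) at the optimal length, FV(0) = 1,
#' and FP is zero at or below the slack length and strictly increasing
#' above it.
#'
#' @param normalized_fiber_length fiber length in optimal-length units
#' @param normalized_fiber_velocity fiber velocity in vmax units
#'   (shortening negative)
#' @param activation activation in `[0, 1]`
#' @param params [muscle_params()]
#' @return force (N), same shape as the inputs
#' @export
hill_force <- function(normalized_fiber_length, normalized_fiber_velocity,
                       activation, params) {
  a <- v_clamp(activation, 0, 1)
  fl <- .fl_curve(normalized_fiber_length, params$fl_width)
  fv <- .fv_curve(normalized_fiber_velocity, params$fv_af, params$fv_flen)
  fp <- .fp_curve(normalized_fiber_length, params$normalized_slack_length,
                  params$pe_shape, params$pe_strain)
  params$max_isometric_force * (a * fl * fv + fp)
}

#' Hill-type muscle parameter set for the six-muscle planar arm
#'
#' Maximum isometric forces, tendon lengths and optimal muscle lengths for
#' the shoulder flexor/extensor (SF/SE), elbow flexor/extensor (EF/EE) and
#' bi-articular flexor/extensor (BF/BE). The elbow-flexor tendon length is
#' 0.172 m (the value consistent with the length polynomials and with the
#' source biomechanical model; see the methods vignette).
#'
#' @return data.frame with one row per muscle
#' @export
arm26_muscle_table <- function() {
  data.frame(
    muscle = c("SF", "SE", "EF", "EE", "BF", "BE"),
    max_isometric_force = c(838, 1207, 1422, 1549, 414, 603),
    tendon_length = c(0.039, 0.066, 0.172, 0.187, 0.204, 0.217),
    optimal_muscle_length = c(0.134, 0.140, 0.092, 0.093, 0.137, 0.127),
    stringsAsFactors = FALSE
  )
}
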