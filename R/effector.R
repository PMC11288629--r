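#' @title Effector: muscles + geometry + skeleton, stepped as one unit
#'
#' @description
#' An effector couples a skeleton, a set of muscle actuators and the
#' muscle-path geometry, and advances them with a shared fixed-step Euler
#' integrator (dt = 0.01 s). One step performs, in order: (1) one Euler
#' step of the excitation-to-activation dynamics; (2) muscle geometry
#' (lengths, velocities, moment arms) at the current configuration;
#' (3) muscle forces; (4) generalized forces = muscle torques plus the
#' Jacobian-transpose image of any external endpoint force; (5) skeleton
#' forward dynamics; (6) Euler update of velocities then positions (the
#' position update uses the updated velocity); (7) refresh of the
#' cartesian and muscle state records at the new configuration. All state
#' is batched (`B x k` matrices) and every stage runs identically on plain
#' numerics or on autodiff nodes, which is what makes policies trainable
#' by backpropagation through the effector.
#'
#' Two presets mirror the package's standard models: [ReluPointMass24()]
#' (planar point-mass, four linear muscles in an 'X') and
#' [RigidTendonArm26()] (two-joint planar arm, six rigid-tendon Hill-type
#' muscles, with either polynomial or path-based moment arms).
#'
#' @name effector_integration
NULL

#' Construct an effector
#'
#' @param skeleton `"two_link"` or `"point_mass"`
#' @param skeleton_params [two_link_params()] or [point_mass_params()]
#' @param muscle_type `"hill"` or `"relu"`
#' @param muscle_table data.frame with per-muscle `max_isometric_force`
#'   and, for Hill muscles, `tendon_length`, `optimal_muscle_length`
#' @param geometry `"polynomial"` (arm only) or `"paths"`
#' @param paths list of [muscle_path()] (required for `geometry = "paths"`)
#' @param poly_coeffs polynomial coefficient table (for `"polynomial"`)
#' @param muscle_config [muscle_params()]-style shared curve constants;
#'   per-muscle fmax/tendon/optimal come from `muscle_table`
#' @param dt integration timestep (s)
#' @param rest_activation activation at reset
#' @return object of class `effector`
#' @export
effector <- function(skeleton, skeleton_params, muscle_type, muscle_table,
                     geometry = c("paths", "polynomial"),
                     paths = NULL, poly_coeffs = NULL,
                     muscle_config = muscle_params(max_isometric_force = 1),
                     dt = 0.01,
                     rest_activation = if (muscle_type == "hill") 1e-3 else 0) {
  geometry <- match.arg(geometry)
  m <- nrow(muscle_table)
  if (geometry == "paths") stopifnot(length(paths) == m)
  if (geometry == "polynomial") stopifnot(nrow(poly_coeffs) == m)
  fmax <- matrix(muscle_table$max_isometric_force, 1L)
  lt <- if (!is.null(muscle_table$tendon_length))
    matrix(muscle_table$tendon_length, 1L) else matrix(0, 1L, m)
  l0 <- if (!is.null(muscle_table$optimal_muscle_length))
    matrix(muscle_table$optimal_muscle_length, 1L) else matrix(1, 1L, m)
  structure(list(
    skeleton = skeleton, P = skeleton_params,
    muscle_type = muscle_type, n_muscles = m,
    muscle_names = if (!is.null(muscle_table$muscle)) muscle_table$muscle
                   else paste0("m", seq_len(m)),
    fmax = fmax, lt = lt, l0 = l0, mc = muscle_config,
    geometry = geometry, paths = paths, poly = poly_coeffs,
    dt = dt, rest_activation = rest_activation,
    dof = skeleton_params$dof
  ), class = "effector")
}

#' Planar point-mass with four linear (ReLU) muscles
#'
#' 1 kg point-mass in a `[-1, 1]^2` workspace, four muscles of maximum
#' isometric force 500 N anchored at the corners `(+-2, +-2)`.
#' @param mass mass (kg)
#' @param fmax maximum isometric force per muscle (N)
#' @return an [effector()]
#' @export
ReluPointMass24 <- function(mass = 1, fmax = 500) {
  effector(
    skeleton = "point_mass", skeleton_params = point_mass_params(mass = mass),
    muscle_type = "relu",
    muscle_table = data.frame(muscle = c("UR", "LR", "LL", "UL"),
                              max_isometric_force = rep(fmax, 4L),
                              # resting path length: used only to scale
                              # proprioceptive feedback
                              optimal_muscle_length = rep(2 * sqrt(2), 4L)),
    geometry = "paths", paths = pointmass_muscle_paths()
  )
}

#' Two-joint planar arm with six rigid-tendon Hill-type muscles
#'
#' @param geometry `"polynomial"` for the moment-arm approximation used in
#'   training studies, `"paths"` for moment arms from the declared muscle
#'   paths (used for the biomechanical-property analyses)
#' @param skeleton_params [two_link_params()]
#' @param muscle_config shared Hill curve constants ([muscle_params()])
#' @return an [effector()]
#' @export
RigidTendonArm26 <- function(geometry = c("polynomial", "paths"),
                             skeleton_params = two_link_params(),
                             muscle_config = muscle_params(max_isometric_force = 1),
                             rest_activation = 1e-3) {
  geometry <- match.arg(geometry)
  effector(
    skeleton = "two_link", skeleton_params = skeleton_params,
    muscle_type = "hill", muscle_table = arm26_muscle_table(),
    geometry = geometry,
    paths = if (geometry == "paths") arm26_muscle_paths(),
    poly_coeffs = if (geometry == "polynomial") arm26_polynomial_table(),
    muscle_config = muscle_config, rest_activation = rest_activation
  )
}

# geometry at configuration q with velocity qdot:
# list(len, vel, ma1, ma2), all B x m
.effector_geometry <- function(eff, q, qdot) {
  st <- list(q = q)
  if (eff$geometry == "polynomial") {
    g <- polynomial_length_and_moment_arms(eff$poly, st)
  } else {
    g <- geometric_moment_arms(eff$paths, st, eff$P)
  }
  qd1 <- v_cols(qdot, 1L); qd2 <- v_cols(qdot, 2L)
  vel <- v_mul(g$ma1, qd1) + v_mul(g$ma2, qd2) # chain rule through geometry
  list(len = g$len, vel = vel, ma1 = g$ma1, ma2 = g$ma2)
}

# muscle forces from activation and geometry; returns list(force, fiber)
.effector_forces <- function(eff, a, geom) {
  if (eff$muscle_type == "relu") {
    force <- v_mul(eff$fmax, v_clamp(a, 0, 1))
    return(list(force = force, fiber_len = NULL, fiber_vel = NULL))
  }
  mc <- eff$mc
  # rigid tendon: fiber = musculotendon minus constant tendon, floored a
  # hair above zero so extreme postures cannot produce a negative length
  fl <- v_clamp(v_mul(v_add(geom$len, -eff$lt), 1 / eff$l0), 0.01, Inf)
  fv <- v_mul(geom$vel, 1 / (mc$vmax * eff$l0))
  flc <- .fl_curve(fl, mc$fl_width)
  fvc <- .fv_curve(fv, mc$fv_af, mc$fv_flen)
  fpc <- .fp_curve(fl, mc$normalized_slack_length, mc$pe_shape, mc$pe_strain)
  force <- v_mul(eff$fmax, v_clamp(a, 0, 1) * flc * fvc + fpc)
  list(force = force, fiber_len = fl, fiber_vel = fv)
}

# per-column clamp of q to joint limits + zeroing of outward velocities
.apply_limits <- function(eff, q, qdot) {
  lo <- eff$P$q_lower; hi <- eff$P$q_upper
  qv <- ad_value(q); qdv <- ad_value(qdot)
  cols_q <- vector("list", eff$dof); cols_qd <- vector("list", eff$dof)
  for (j in seq_len(eff$dof)) {
    cj <- v_clamp(v_cols(q, j), lo[j], hi[j])
    out_lo <- (qv[, j] <= lo[j]) & (qdv[, j] < 0)
    out_hi <- (qv[, j] >= hi[j]) & (qdv[, j] > 0)
    keep <- matrix(1 - ((out_lo | out_hi) * 1), nrow(qv), 1L)
    cols_q[[j]] <- cj
    cols_qd[[j]] <- v_cols(qdot, j) * keep
  }
  list(q = do.call(v_cbind, cols_q), qdot = do.call(v_cbind, cols_qd))
}

.cartesian <- function(eff, q, qdot) {
  st <- list(q = q, qdot = qdot)
  if (eff$skeleton == "two_link") forward_kinematics(st, eff$P)
  else point_mass_kinematics(st)
}

#' Reset an effector to a posture (or sample postures)
#'
#' Velocities are zeroed, activations set to the resting value, and the
#' geometry/cartesian records are made consistent with the posture. With
#' `joint_position = NULL`, postures are drawn uniformly over the
#' joint-limit box.
#'
#' @param eff [effector()]
#' @param joint_position `B x dof` matrix (or dof-vector) of coordinates,
#'   or NULL to sample
#' @param batch_size number of parallel states when sampling
#' @param seed optional integer seed for the sampler
#' @return effector state: list with `q`, `qdot`, `a`, `geom`, `fiber_len`,
#'   `fiber_vel`, `force`, `cart`, `action`
#' @export
effector_reset <- function(eff, joint_position = NULL, batch_size = 1L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lo <- eff$P$q_lower; hi <- eff$P$q_upper
  if (is.null(joint_position)) {
    q <- sapply(seq_len(eff$dof),
                function(j) stats::runif(batch_size, lo[j], hi[j]))
    q <- matrix(q, batch_size, eff$dof)
  } else {
    q <- if (is.matrix(joint_position)) joint_position
         else matrix(joint_position, nrow = 1L)
    if (any(sweep(q, 2, lo, "<") | sweep(q, 2, hi, ">")))
      stop("requested joint position outside joint limits", call. = FALSE)
  }
  B <- nrow(q)
  qdot <- matrix(0, B, eff$dof)
  a <- matrix(eff$rest_activation, B, eff$n_muscles)
  geom <- .effector_geometry(eff, q, qdot)
  frc <- .effector_forces(eff, a, geom)
  list(q = q, qdot = qdot, a = a, geom = geom,
       fiber_len = frc$fiber_len, fiber_vel = frc$fiber_vel,
       force = frc$force, cart = .cartesian(eff, q, qdot),
       action = matrix(0, B, eff$n_muscles))
}

#' Advance an effector by one timestep
#'
#' @param eff [effector()]
#' @param state effector state from [effector_reset()] or a previous step
#' @param action `B x m` action (excitation) matrix; clipped to `[0, 1]`
#'   by the activation dynamics
#' @param external_force optional `B x 2` external force applied at the
#'   endpoint (N); mapped to generalized forces through the endpoint
#'   Jacobian transpose
#' @param engine `"auto"` uses the fused single-node autodiff kernel for
#'   the standard effectors when inputs are being recorded; `"primitive"`
#'   forces the elementary-op route (slower; used as the gradient oracle)
#' @return new effector state
#' @export
effector_step <- function(eff, state, action, external_force = NULL,
                          engine = c("auto", "primitive")) {
  engine <- match.arg(engine)
  recording <- is.advar(state$q) || is.advar(state$a) || is.advar(action)
  if (engine == "auto" && recording && .fused_capable(eff))
    return(.fused_effector_step(eff, state, action, external_force))
  dt <- eff$dt
  .check <- function(x, stage) {
    if (any(!is.finite(ad_value(x))))
      stop("non-finite values at stage: ", stage, call. = FALSE)
  }
  # (1) activation dynamics
  da <- activation_derivative(action, state$a, eff$mc$tau_act, eff$mc$tau_deact)
  a_new <- v_clamp(euler_step(state$a, da, dt), 0, 1)
  # (2) geometry at the current configuration (cached from the previous
  # refresh) and (3) muscle force
  geom <- state$geom
  frc <- .effector_forces(eff, a_new, geom)
  .check(frc$force, "muscle force")
  # (4) generalized forces
  tau <- .muscle_torque_batch(list(geom$ma1, geom$ma2), frc$force)
  if (!is.null(external_force)) {
    if (eff$skeleton == "two_link") {
      J <- two_link_jacobian(state$q, eff$P)
      fx <- v_cols(external_force, 1L); fy <- v_cols(external_force, 2L)
      tau_ext <- v_cbind(v_cols(J, 1L) * fx + v_cols(J, 3L) * fy,
                         v_cols(J, 2L) * fx + v_cols(J, 4L) * fy)
    } else {
      tau_ext <- external_force
    }
    tau <- tau + tau_ext
  }
  # (5) skeleton dynamics
  st <- list(q = state$q, qdot = state$qdot)
  qacc <- if (eff$skeleton == "two_link") two_link_dynamics(st, tau, eff$P)
          else point_mass_dynamics(st, tau, eff$P)
  .check(qacc, "skeleton dynamics")
  # (6) integrate velocity, then position with the updated velocity
  qdot_new <- euler_step(state$qdot, qacc, dt)
  q_new <- euler_step(state$q, qdot_new, dt)
  lim <- .apply_limits(eff, q_new, qdot_new)
  # (7) refresh records at the new configuration
  geom_new <- .effector_geometry(eff, lim$q, lim$qdot)
  frc_new <- .effector_forces(eff, a_new, geom_new)
  list(q = lim$q, qdot = lim$qdot, a = a_new, geom = geom_new,
       fiber_len = frc_new$fiber_len, fiber_vel = frc_new$fiber_vel,
       force = frc_new$force, cart = .cartesian(eff, lim$q, lim$qdot),
       action = action)
}
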