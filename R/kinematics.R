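#' @title Skeletons: planar point-mass and two-joint arm
#'
#' @description
#' Rigid-body layer of the effector. Two skeletons are provided:
#'
#' * a planar point-mass with generalized coordinates `(x, y)` in metres,
#'   obeying `xddot = f / m`;
#' * a planar two-link arm (shoulder + elbow hinge, no gravity -- the arm
#'   moves in a horizontal plane) with generalized coordinates
#'   `q = (shoulder, elbow)` in radians, positive flexion increasing the
#'   angle, and dynamics `M(q) qddot + c(q, qdot) + B qdot = tau` where
#'   `M` is the configuration-dependent inertia matrix and `c` the
#'   Coriolis/centripetal vector.
#'
#' All dynamics functions are batch-vectorized: states are `B x dof`
#' matrices and work both on plain numerics and on autodiff nodes, so the
#' same code path serves plain simulation and gradient-based training.
#'
#' @name kinematics
NULL

#' Two-link arm skeleton parameters
#'
#' Defaults are the planar arm segment parameters used throughout the
#' package (upper arm: 1.82 kg, CoG 0.135 m, inertia 0.051 kg m^2, length
#' 0.309 m; forearm: 1.43 kg, 0.165 m, 0.057 kg m^2, 0.333 m).
#'
#' @param m1,m2 segment masses (kg)
#' @param d1,d2 centre-of-gravity distances from the proximal joint (m)
#' @param I1,I2 segment inertias about their centre of gravity (kg m^2)
#' @param L1,L2 segment lengths (m)
#' @param viscosity 2x2 joint viscosity matrix B (N m s / rad); default zero
#' @param q_lower,q_upper joint angle limits (rad); defaults shoulder
#'   `[0, 135 deg]`, elbow `[0, 155 deg]`
#' @return object of class `two_link_params`
#' @export
two_link_params <- function(m1 = 1.82, d1 = 0.135, I1 = 0.051, L1 = 0.309,
                            m2 = 1.43, d2 = 0.165, I2 = 0.057, L2 = 0.333,
                            viscosity = matrix(0, 2, 2),
                            q_lower = c(0, 0),
                            q_upper = c(135, 155) * pi / 180) {
  stopifnot(m1 > 0, m2 > 0, d1 > 0, d2 > 0, I1 > 0, I2 > 0, L1 > 0, L2 > 0)
  viscosity <- as.matrix(viscosity)
  stopifnot(identical(dim(viscosity), c(2L, 2L)),
            isTRUE(all.equal(viscosity, t(viscosity))),
            all(eigen(viscosity, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  structure(list(m1 = m1, d1 = d1, I1 = I1, L1 = L1,
                 m2 = m2, d2 = d2, I2 = I2, L2 = L2,
                 viscosity = viscosity,
                 q_lower = q_lower, q_upper = q_upper,
                 dof = 2L),
            class = "two_link_params")
}

#' Point-mass skeleton parameters
#'
#' @param mass mass (kg); default 1
#' @param bounds 2x2 workspace bounds matrix, rows = (x, y), cols =
#'   (lower, upper) in metres; default the unit square `[-1, 1]^2`
#' @return object of class `point_mass_params`
#' @export
point_mass_params <- function(mass = 1,
                              bounds = rbind(c(-1, 1), c(-1, 1))) {
  stopifnot(mass > 0, identical(dim(as.matrix(bounds)), c(2L, 2L)))
  structure(list(mass = mass, bounds = as.matrix(bounds),
                 q_lower = bounds[, 1L], q_upper = bounds[, 2L], dof = 2L),
            class = "point_mass_params")
}

#' Joint state constructor
#'
#' @param q generalized coordinates, `B x dof` matrix (or vector for B = 1)
#' @param qdot generalized velocities, same shape
#' @return list with matrices `q`, `qdot`
#' @export
joint_state <- function(q, qdot = NULL) {
  if (!is.matrix(q) && !is.advar(q)) q <- matrix(q, nrow = 1L)
  if (is.null(qdot)) qdot <- matrix(0, nrow(ad_value(q)), ncol(ad_value(q)))
  if (!is.matrix(qdot) && !is.advar(qdot)) qdot <- matrix(qdot, nrow = 1L)
  stopifnot(all(dim(ad_value(q)) == dim(ad_value(qdot))))
  list(q = q, qdot = qdot)
}

#' Point-mass dynamics
#'
#' Newton's law for the planar point-mass: acceleration = force / mass.
#'
#' @param state joint state (unused by the dynamics; kept for a uniform
#'   skeleton interface)
#' @param force `B x 2` applied force (N)
#' @param params [point_mass_params()]
#' @return `B x 2` acceleration (m/s^2)
#' @export
point_mass_dynamics <- function(state, force, params = point_mass_params()) {
  fv <- ad_value(force)
  if (!all(is.finite(fv))) stop("non-finite force", call. = FALSE)
  force / params$mass
}

# inertia-matrix entries for a batch of configurations; q is B x 2
.two_link_M <- function(q, P) {
  c2 <- cos(v_cols(q, 2L))
  m11 <- P$I1 + P$I2 + P$m1 * P$d1^2 +
    P$m2 * (P$L1^2 + P$d2^2) + (2 * P$m2 * P$L1 * P$d2) * c2
  m12 <- P$I2 + P$m2 * P$d2^2 + (P$m2 * P$L1 * P$d2) * c2
  m22v <- P$I2 + P$m2 * P$d2^2
  list(m11 = m11, m12 = m12, m22 = m22v)
}

#' Two-link arm inverse-inertia dynamics
#'
#' Solves `M(q) qddot = tau - c(q, qdot) - B qdot` for the planar two-link
#' chain (horizontal plane, no gravity). The 2x2 solve is done in closed
#' form per batch row, which keeps the operation differentiable.
#'
#' @param state joint state with `q`, `qdot` as `B x 2` matrices (rad, rad/s)
#' @param torque `B x 2` joint torques (N m)
#' @param params [two_link_params()]
#' @return `B x 2` joint accelerations (rad/s^2)
#' @export
two_link_dynamics <- function(state, torque, params = two_link_params()) {
  tv <- ad_value(torque)
  if (!all(is.finite(tv))) stop("non-finite torque", call. = FALSE)
  q <- state$q; qd <- state$qdot
  M <- .two_link_M(q, params)
  h <- params$m2 * params$L1 * params$d2
  s2 <- sin(v_cols(q, 2L))
  qd1 <- v_cols(qd, 1L); qd2 <- v_cols(qd, 2L)
  # Coriolis/centripetal vector
  c1 <- -h * s2 * (2 * qd1 * qd2 + qd2 * qd2)
  c2v <- h * s2 * (qd1 * qd1)
  Bv <- params$viscosity
  rhs1 <- v_cols(torque, 1L) - c1 - (Bv[1, 1] * qd1 + Bv[1, 2] * qd2)
  rhs2 <- v_cols(torque, 2L) - c2v - (Bv[2, 1] * qd1 + Bv[2, 2] * qd2)
  det <- M$m11 * M$m22 - M$m12 * M$m12
  dv <- ad_value(det)
  if (any(dv <= 0)) stop("singular inertia matrix", call. = FALSE)
  qdd1 <- (M$m22 * rhs1 - M$m12 * rhs2) / det
  qdd2 <- (M$m11 * rhs2 - M$m12 * rhs1) / det
  v_cbind(qdd1, qdd2)
}

#' Forward kinematics of the two-link arm
#'
#' Endpoint position from joint angles and endpoint velocity through the
#' analytic Jacobian. The point-mass analogue is the identity map (see
#' [point_mass_kinematics()]).
#'
#' @param state joint state (`B x 2` matrices)
#' @param params [two_link_params()]
#' @return list with `pos` (`B x 2`, m) and `vel` (`B x 2`, m/s)
#' @export
forward_kinematics <- function(state, params = two_link_params()) {
  q1 <- v_cols(state$q, 1L); q12 <- q1 + v_cols(state$q, 2L)
  qd1 <- v_cols(state$qdot, 1L); qd12 <- qd1 + v_cols(state$qdot, 2L)
  c1 <- cos(q1); s1 <- sin(q1); c12 <- cos(q12); s12 <- sin(q12)
  x <- params$L1 * c1 + params$L2 * c12
  y <- params$L1 * s1 + params$L2 * s12
  vx <- -params$L1 * s1 * qd1 - params$L2 * s12 * qd12
  vy <- params$L1 * c1 * qd1 + params$L2 * c12 * qd12
  list(pos = v_cbind(x, y), vel = v_cbind(vx, vy))
}

#' Endpoint Jacobian of the two-link arm
#'
#' @param q `B x 2` joint angles (plain numeric)
#' @return `B x 4` matrix with columns (J11, J12, J21, J22) of
#'   `d(endpoint)/d(q)`; row-wise 2x2 Jacobians
#' @export
two_link_jacobian <- function(q, params = two_link_params()) {
  q1 <- v_cols(q, 1L); q12 <- q1 + v_cols(q, 2L)
  s1 <- sin(q1); c1 <- cos(q1); s12 <- sin(q12); c12 <- cos(q12)
  J11 <- -params$L1 * s1 - params$L2 * s12
  J12 <- -params$L2 * s12
  J21 <- params$L1 * c1 + params$L2 * c12
  J22 <- params$L2 * c12
  v_cbind(J11, J12, J21, J22)
}

#' Cartesian state of the point-mass (identity kinematics)
#' @param state joint state
#' @return list with `pos`, `vel`
#' @export
point_mass_kinematics <- function(state) list(pos = state$q, vel = state$qdot)

#' One explicit-Euler integration step
#'
#' @param value current value (matrix or `advar`)
#' @param derivative time derivative, same shape
#' @param dt timestep (s), default 0.01
#' @return `value + dt * derivative`
#' @export
euler_step <- function(value, derivative, dt = 0.01) {
  dv <- dim(ad_value(value)); dd <- dim(ad_value(derivative))
  if (!all(dv == dd)) stop("shape mismatch in euler_step", call. = FALSE)
  value + dt * derivative
}

#' Kinetic energy of the two-link arm
#'
#' Computed from the inertia matrix: `T = 0.5 qdot' M(q) qdot`. Used by the
#' energy-conservation integrator checks.
#' @param state joint state (plain numeric)
#' @param params [two_link_params()]
#' @return `B x 1` kinetic energy (J)
#' @export
two_link_kinetic_energy <- function(state, params = two_link_params()) {
  M <- .two_link_M(state$q, params)
  qd1 <- v_cols(state$qdot, 1L); qd2 <- v_cols(state$qdot, 2L)
  0.5 * (M$m11 * qd1^2 + 2 * M$m12 * qd1 * qd2 + M$m22 * qd2^2)
}
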