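# Shared oracles and fixtures. Oracles are deliberately written from
# scratch (finite differences, energy-based mechanics) so they stay
# independent of the implementation paths they check.

# central finite-difference gradient of a scalar function of a matrix
fd_grad <- function(fn, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    e <- x * 0; e[i] <- h
    g[i] <- (fn(x + e) - fn(x - e)) / (2 * h)
  }
  g
}

# Independent two-link equations of motion via Lagrangian mechanics.
# Kinetic energy is assembled from segment centre-of-mass velocities and
# angular rates; M comes from finite differences of T in qdot (exact up
# to roundoff since T is quadratic in qdot), the velocity-product terms
# from finite differences of the generalized momenta in q.
lagrangian_qacc <- function(q, qd, tau, P) {
  Tfun <- function(q, qd) {
    c1 <- cos(q[1]); s1 <- sin(q[1])
    c12 <- cos(q[1] + q[2]); s12 <- sin(q[1] + q[2])
    v1 <- P$d1 * qd[1] * c(-s1, c1)
    v2 <- P$L1 * qd[1] * c(-s1, c1) + P$d2 * (qd[1] + qd[2]) * c(-s12, c12)
    0.5 * P$m1 * sum(v1^2) + 0.5 * P$I1 * qd[1]^2 +
      0.5 * P$m2 * sum(v2^2) + 0.5 * P$I2 * (qd[1] + qd[2])^2
  }
  # T is exactly quadratic in qdot, so velocity differences are exact for
  # any step size; a large step keeps roundoff negligible
  hqd <- 0.5
  M <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- c(0, 0); ei[i] <- hqd
    ej <- c(0, 0); ej[j] <- hqd
    M[i, j] <- (Tfun(q, qd + ei + ej) - Tfun(q, qd + ei - ej) -
                  Tfun(q, qd - ei + ej) + Tfun(q, qd - ei - ej)) / (4 * hqd^2)
  }
  p_of_q <- function(qq) {
    vapply(1:2, function(i) {
      e <- c(0, 0); e[i] <- hqd
      (Tfun(qq, qd + e) - Tfun(qq, qd - e)) / (2 * hqd)
    }, numeric(1))
  }
  # q-derivatives are trigonometric: Richardson-extrapolated central
  # differences give O(h^4) truncation with h large enough to avoid
  # roundoff
  rich <- function(f, h) {
    d <- function(hh) (f(hh) - f(-hh)) / (2 * hh)
    (4 * d(h / 2) - d(h)) / 3
  }
  hq <- 1e-3
  dpdq <- matrix(0, 2, 2)
  dTdq <- numeric(2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- 1
    dpdq[, j] <- rich(function(hh) p_of_q(q + hh * e), hq)
    dTdq[j] <- rich(function(hh) Tfun(q + hh * e, qd), hq)
  }
  b <- as.numeric(dpdq %*% qd) - dTdq # Coriolis/centripetal terms
  solve(M, tau - b - as.numeric(P$viscosity %*% qd))
}

# small deterministic environments for fast tests
tiny_arm_env <- function(horizon = 0.1, ...)
  RandomReach(RigidTendonArm26(), horizon = horizon, ...)

tiny_pm_env <- function(horizon = 0.1, ...)
  RandomReach(ReluPointMass24(), horizon = horizon, ...)

deg <- function(x) x * pi / 180
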