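# Fused autodiff kernels for the hot path of training rollouts.
#
# The primitive-op route (effector_step / policy_forward on advar inputs)
# records a few hundred tape nodes per timestep, which dominates runtime in
# long batched rollouts. The kernels below compute one whole effector or GRU
# step as a *single* tape node with a hand-derived vector-Jacobian product.
# They are mathematically identical to the primitive route -- masks use the
# same strict inequalities as v_clamp, so even subgradients at kinks agree
# bit-for-bit -- and the test suite checks both values and gradients of the
# two routes against each other and against finite differences.
#
# State layout of the fused step node output (B x K):
#   [activations (m)] [q (2)] [qdot (2)] [cart pos (2)] [cart vel (2)]
#   [normalized muscle lengths (m)] [normalized muscle velocities (m)]

.fused_layout <- function(m) {
  list(ia = seq_len(m), iq = m + 1:2, iqd = m + 3:4,
       icp = m + 5:6, icv = m + 7:8,
       ipl = m + 8L + seq_len(m), ipv = 2L * m + 8L + seq_len(m),
       K = 3L * m + 8L)
}

.fused_capable <- function(eff) {
  (eff$skeleton == "two_link" && eff$geometry == "polynomial" &&
     eff$muscle_type == "hill") ||
    (eff$skeleton == "point_mass" && eff$geometry == "paths" &&
       eff$muscle_type == "relu")
}

# activation update shared by both effectors: returns value + partials
.fused_activation <- function(av, actv, dt, tact, tdeact) {
  u <- pmin(pmax(actv, 0), 1)
  mu <- (actv > 0 & actv < 1) * 1
  rising <- (u > av) * 1
  tau <- rising * tact + (1 - rising) * tdeact
  a1p <- av + dt * (u - av) / tau
  a1 <- pmin(pmax(a1p, 0), 1)
  m1 <- (a1p > 0 & a1p < 1) * 1
  list(a1 = a1,
       d_a = m1 * (1 - dt / tau),   # da1/da
       d_act = m1 * (dt / tau) * mu) # da1/daction
}

# concatenate an effector state into the fused B x K layout (plain values)
.state_concat <- function(eff, state) {
  pr <- ad_value(.prop_block(eff, state))
  cbind(ad_value(state$a), ad_value(state$q), ad_value(state$qdot),
        ad_value(state$cart$pos), ad_value(state$cart$vel), pr)
}

# one fused step of the six-muscle polynomial-geometry arm.
# src: B x K state (advar or plain); action: B x m; fext: B x 2 or NULL.
.fused_step_arm <- function(eff, src, action, fext = NULL) {
  P <- eff$P; mc <- eff$mc; dt <- eff$dt
  m <- eff$n_muscles
  L <- .fused_layout(m)
  sv <- ad_value(src)
  av <- sv[, L$ia, drop = FALSE]
  qv <- sv[, L$iq, drop = FALSE]
  qdv <- sv[, L$iqd, drop = FALSE]
  actv <- ad_value(action)
  fev <- if (is.null(fext)) NULL else ad_value(fext)
  B <- nrow(av)
  a0r <- eff$poly$a0; a1sr <- eff$poly$a1s
  a1er <- eff$poly$a1e; a2er <- eff$poly$a2e
  ltm <- matrix(eff$lt, B, m, byrow = TRUE)
  l0m <- matrix(eff$l0, B, m, byrow = TRUE)
  fmaxm <- matrix(eff$fmax, B, m, byrow = TRUE)
  a2em <- matrix(a2er, B, m, byrow = TRUE)
  ma1 <- matrix(a1sr, B, m, byrow = TRUE)

  ## ---- forward ----
  ac <- .fused_activation(av, actv, dt, mc$tau_act, mc$tau_deact)
  a1 <- ac$a1
  q1 <- qv[, 1L]; q2 <- qv[, 2L]; qd1 <- qdv[, 1L]; qd2 <- qdv[, 2L]
  geo <- function(ts, te, td1, td2) {
    len <- matrix(a0r, B, m, byrow = TRUE) + outer(ts, a1sr) +
      outer(te, a1er) + outer(te^2, a2er)
    ma2 <- matrix(a1er, B, m, byrow = TRUE) + 2 * outer(te, a2er)
    vel <- ma1 * td1 + ma2 * td2
    list(len = len, ma2 = ma2, vel = vel)
  }
  g0 <- geo(q1, q2, qd1, qd2)
  flp <- (g0$len - ltm) / l0m
  fl <- pmax(flp, 0.01); mfl <- (flp > 0.01) * 1
  vn <- g0$vel / (mc$vmax * l0m)
  FLc <- exp(-((fl - 1)^2) / mc$fl_width)
  dFL <- FLc * (-2 * (fl - 1) / mc$fl_width)
  af <- mc$fv_af; flen <- mc$fv_flen
  vc <- pmin(pmax(vn, -1), 0); mvc <- (vn > -1 & vn < 0) * 1
  ve <- pmax(vn, 0); mve <- (vn > 0) * 1
  conc <- (1 + vc) / (1 - vc / af)
  dconc <- (1 + 1 / af) / (1 - vc / af)^2 * mvc
  ce <- 2 + 2 / af
  den <- ve * ce + (flen - 1)
  ecc <- (flen * ve * ce + (flen - 1)) / den
  decc <- ce * (flen - 1)^2 / den^2 * mve
  sh <- (vn <= 0) * 1
  FVc <- sh * conc + (1 - sh) * ecc
  mFV <- (FVc > 0 & FVc < flen) * 1
  dFV <- (sh * dconc + (1 - sh) * decc) * mFV
  ss <- pmax(fl - mc$normalized_slack_length, 0) / mc$pe_strain
  msl <- (fl > mc$normalized_slack_length) * 1
  eks <- exp(mc$pe_shape * ss); ekden <- exp(mc$pe_shape) - 1
  FPc <- (eks - 1) / ekden
  dFP <- msl * (mc$pe_shape / mc$pe_strain) * eks / ekden
  ma_in <- (a1 > 0 & a1 < 1) * 1 # inner clamp in the force law
  Fm <- fmaxm * (a1 * FLc * FVc + FPc)
  tau1 <- -rowSums(ma1 * Fm); tau2 <- -rowSums(g0$ma2 * Fm)
  if (!is.null(fev)) {
    s1 <- sin(q1); c1 <- cos(q1); s12 <- sin(q1 + q2); c12 <- cos(q1 + q2)
    J11 <- -P$L1 * s1 - P$L2 * s12; J12 <- -P$L2 * s12
    J21 <- P$L1 * c1 + P$L2 * c12; J22 <- P$L2 * c12
    fx <- fev[, 1L]; fy <- fev[, 2L]
    tau1 <- tau1 + J11 * fx + J21 * fy
    tau2 <- tau2 + J12 * fx + J22 * fy
  }
  hC <- P$m2 * P$L1 * P$d2
  Acon <- P$I1 + P$I2 + P$m1 * P$d1^2 + P$m2 * (P$L1^2 + P$d2^2)
  Ccon <- P$I2 + P$m2 * P$d2^2
  c2 <- cos(q2); s2 <- sin(q2)
  m11 <- Acon + 2 * hC * c2; m12 <- Ccon + hC * c2; m22 <- Ccon
  cor1 <- -hC * s2 * (2 * qd1 * qd2 + qd2^2)
  cor2 <- hC * s2 * qd1^2
  Bv <- P$viscosity
  rhs1 <- tau1 - cor1 - (Bv[1, 1] * qd1 + Bv[1, 2] * qd2)
  rhs2 <- tau2 - cor2 - (Bv[2, 1] * qd1 + Bv[2, 2] * qd2)
  det <- m11 * m22 - m12^2
  qdd1 <- (m22 * rhs1 - m12 * rhs2) / det
  qdd2 <- (m11 * rhs2 - m12 * rhs1) / det
  qd1np <- qd1 + dt * qdd1; qd2np <- qd2 + dt * qdd2
  q1np <- q1 + dt * qd1np; q2np <- q2 + dt * qd2np
  lo <- P$q_lower; hi <- P$q_upper
  q1n <- pmin(pmax(q1np, lo[1]), hi[1]); mq1 <- (q1np > lo[1] & q1np < hi[1]) * 1
  q2n <- pmin(pmax(q2np, lo[2]), hi[2]); mq2 <- (q2np > lo[2] & q2np < hi[2]) * 1
  k1 <- 1 - ((q1np <= lo[1] & qd1np < 0) | (q1np >= hi[1] & qd1np > 0)) * 1
  k2 <- 1 - ((q2np <= lo[2] & qd2np < 0) | (q2np >= hi[2] & qd2np > 0)) * 1
  qd1n <- qd1np * k1; qd2n <- qd2np * k2
  # records at the new configuration
  g1 <- geo(q1n, q2n, qd1n, qd2n)
  pl <- g1$len / l0m; pv <- g1$vel / l0m
  s1n <- sin(q1n); c1n <- cos(q1n)
  s12n <- sin(q1n + q2n); c12n <- cos(q1n + q2n)
  qdsn <- qd1n + qd2n
  cpx <- P$L1 * c1n + P$L2 * c12n; cpy <- P$L1 * s1n + P$L2 * s12n
  cvx <- -P$L1 * s1n * qd1n - P$L2 * s12n * qdsn
  cvy <- P$L1 * c1n * qd1n + P$L2 * c12n * qdsn
  out <- cbind(a1, q1n, q2n, qd1n, qd2n, cpx, cpy, cvx, cvy, pl, pv)
  if (any(!is.finite(out)))
    stop("non-finite values in fused effector step", call. = FALSE)

  parents <- list(); tags <- character(0)
  addp <- function(x, tag) {
    if (is.advar(x)) { parents[[length(parents) + 1L]] <<- x
                       tags <<- c(tags, tag) }
  }
  addp(src, "src"); addp(action, "act")
  if (!is.null(fext)) addp(fext, "fext")

  ## ---- backward ----
  vjp <- function(G) {
    ga1 <- G[, L$ia, drop = FALSE]
    gq1n <- G[, L$iq[1]]; gq2n <- G[, L$iq[2]]
    gqd1n <- G[, L$iqd[1]]; gqd2n <- G[, L$iqd[2]]
    gcpx <- G[, L$icp[1]]; gcpy <- G[, L$icp[2]]
    gcvx <- G[, L$icv[1]]; gcvy <- G[, L$icv[2]]
    glen2 <- G[, L$ipl, drop = FALSE] / l0m
    gvel2 <- G[, L$ipv, drop = FALSE] / l0m
    # cartesian records at the new state
    gq1n <- gq1n +
      gcpx * (-P$L1 * s1n - P$L2 * s12n) + gcpy * (P$L1 * c1n + P$L2 * c12n) +
      gcvx * (-P$L1 * c1n * qd1n - P$L2 * c12n * qdsn) +
      gcvy * (-P$L1 * s1n * qd1n - P$L2 * s12n * qdsn)
    gq2n <- gq2n +
      gcpx * (-P$L2 * s12n) + gcpy * (P$L2 * c12n) +
      gcvx * (-P$L2 * c12n * qdsn) + gcvy * (-P$L2 * s12n * qdsn)
    gqd1n <- gqd1n +
      gcvx * (-P$L1 * s1n - P$L2 * s12n) + gcvy * (P$L1 * c1n + P$L2 * c12n)
    gqd2n <- gqd2n + gcvx * (-P$L2 * s12n) + gcvy * (P$L2 * c12n)
    # proprioceptive records at the new state
    gq1n <- gq1n + rowSums(glen2 * ma1)
    gq2n <- gq2n + rowSums(glen2 * g1$ma2) + rowSums(gvel2 * 2 * a2em) * qd2n
    gqd1n <- gqd1n + rowSums(gvel2 * ma1)
    gqd2n <- gqd2n + rowSums(gvel2 * g1$ma2)
    # joint limits
    gq1np <- gq1n * mq1; gq2np <- gq2n * mq2
    gqd1np <- gqd1n * k1 + dt * gq1np
    gqd2np <- gqd2n * k2 + dt * gq2np
    # integration
    gq1 <- gq1np; gq2 <- gq2np
    gqd1 <- gqd1np; gqd2 <- gqd2np
    gqdd1 <- dt * gqd1np; gqdd2 <- dt * gqd2np
    # dynamics solve
    grhs1 <- (gqdd1 * m22 - gqdd2 * m12) / det
    grhs2 <- (gqdd2 * m11 - gqdd1 * m12) / det
    gdet <- -(gqdd1 * qdd1 + gqdd2 * qdd2) / det
    gm11 <- gqdd2 * rhs2 / det + gdet * m22
    gm12 <- -(gqdd1 * rhs2 + gqdd2 * rhs1) / det - 2 * gdet * m12
    gq2 <- gq2 + gm11 * (-2 * hC * s2) + gm12 * (-hC * s2)
    gcor1 <- -grhs1; gcor2 <- -grhs2
    gq2 <- gq2 + gcor1 * (-hC * c2 * (2 * qd1 * qd2 + qd2^2)) +
      gcor2 * (hC * c2 * qd1^2)
    gqd1 <- gqd1 + gcor1 * (-2 * hC * s2 * qd2) + gcor2 * (2 * hC * s2 * qd1) -
      (Bv[1, 1] * grhs1 + Bv[2, 1] * grhs2)
    gqd2 <- gqd2 + gcor1 * (-2 * hC * s2 * (qd1 + qd2)) -
      (Bv[1, 2] * grhs1 + Bv[2, 2] * grhs2)
    gtau1 <- grhs1; gtau2 <- grhs2
    gfe <- NULL
    if (!is.null(fev)) {
      gfe <- cbind(gtau1 * J11 + gtau2 * J12, gtau1 * J21 + gtau2 * J22)
      gq1 <- gq1 +
        gtau1 * (fx * (-P$L1 * c1 - P$L2 * c12) + fy * (-P$L1 * s1 - P$L2 * s12)) +
        gtau2 * (fx * (-P$L2 * c12) + fy * (-P$L2 * s12))
      gq2 <- gq2 +
        gtau1 * (fx * (-P$L2 * c12) + fy * (-P$L2 * s12)) +
        gtau2 * (fx * (-P$L2 * c12) + fy * (-P$L2 * s12))
    }
    # muscle torques (ma2 depends on q2)
    gF <- -(ma1 * gtau1 + g0$ma2 * gtau2)
    gq2 <- gq2 - gtau2 * rowSums(2 * a2em * Fm)
    # force law
    ga1t <- ga1 + gF * fmaxm * FLc * FVc * ma_in
    gfl <- gF * fmaxm * (a1 * dFL * FVc + dFP)
    gvn <- gF * fmaxm * (a1 * FLc * dFV)
    glen <- gfl * mfl / l0m
    gvel <- gvn / (mc$vmax * l0m)
    # geometry at the old configuration
    gq1 <- gq1 + rowSums(glen * ma1)
    gq2 <- gq2 + rowSums(glen * g0$ma2) + rowSums(gvel * 2 * a2em) * qd2
    gqd1 <- gqd1 + rowSums(gvel * ma1)
    gqd2 <- gqd2 + rowSums(gvel * g0$ma2)
    # activation dynamics
    ga <- ga1t * ac$d_a
    gact <- ga1t * ac$d_act
    gsrc <- matrix(0, nrow(G), L$K)
    gsrc[, L$ia] <- ga
    gsrc[, L$iq] <- cbind(gq1, gq2)
    gsrc[, L$iqd] <- cbind(gqd1, gqd2)
    all_g <- list(src = gsrc, act = gact, fext = gfe)
    all_g[tags]
  }
  .ad_node(out, parents, vjp)
}

# one fused step of the four-muscle point-mass ('X' anchors, ReLU muscles)
.fused_step_pm <- function(eff, src, action, fext = NULL) {
  P <- eff$P; mc <- eff$mc; dt <- eff$dt
  m <- eff$n_muscles
  L <- .fused_layout(m)
  sv <- ad_value(src)
  av <- sv[, L$ia, drop = FALSE]
  qv <- sv[, L$iq, drop = FALSE]
  qdv <- sv[, L$iqd, drop = FALSE]
  actv <- ad_value(action)
  fev <- if (is.null(fext)) NULL else ad_value(fext)
  B <- nrow(av)
  ax <- vapply(eff$paths, function(p) p$x[1L], numeric(1L))
  ay <- vapply(eff$paths, function(p) p$y[1L], numeric(1L))
  l0m <- matrix(eff$l0, B, m, byrow = TRUE)
  fmaxm <- matrix(eff$fmax, B, m, byrow = TRUE)

  ac <- .fused_activation(av, actv, dt, mc$tau_act, mc$tau_deact)
  a1 <- ac$a1
  q1 <- qv[, 1L]; q2 <- qv[, 2L]; qd1 <- qdv[, 1L]; qd2 <- qdv[, 2L]
  geo <- function(x, y) {
    px <- outer(x, ax, function(a_, b_) a_ - b_)
    py <- outer(y, ay, function(a_, b_) a_ - b_)
    len <- sqrt(px^2 + py^2)
    list(ux = px / len, uy = py / len, len = len)
  }
  g0 <- geo(q1, q2)
  mrelu <- (a1 > 0 & a1 < 1) * 1
  Fm <- fmaxm * a1
  tau1 <- -rowSums(g0$ux * Fm); tau2 <- -rowSums(g0$uy * Fm)
  if (!is.null(fev)) { tau1 <- tau1 + fev[, 1L]; tau2 <- tau2 + fev[, 2L] }
  qdd1 <- tau1 / P$mass; qdd2 <- tau2 / P$mass
  qd1np <- qd1 + dt * qdd1; qd2np <- qd2 + dt * qdd2
  q1np <- q1 + dt * qd1np; q2np <- q2 + dt * qd2np
  lo <- P$q_lower; hi <- P$q_upper
  q1n <- pmin(pmax(q1np, lo[1]), hi[1]); mq1 <- (q1np > lo[1] & q1np < hi[1]) * 1
  q2n <- pmin(pmax(q2np, lo[2]), hi[2]); mq2 <- (q2np > lo[2] & q2np < hi[2]) * 1
  k1 <- 1 - ((q1np <= lo[1] & qd1np < 0) | (q1np >= hi[1] & qd1np > 0)) * 1
  k2 <- 1 - ((q2np <= lo[2] & qd2np < 0) | (q2np >= hi[2] & qd2np > 0)) * 1
  qd1n <- qd1np * k1; qd2n <- qd2np * k2
  g1 <- geo(q1n, q2n)
  vel2 <- g1$ux * qd1n + g1$uy * qd2n
  pl <- g1$len / l0m; pv <- vel2 / l0m
  out <- cbind(a1, q1n, q2n, qd1n, qd2n, q1n, q2n, qd1n, qd2n, pl, pv)
  if (any(!is.finite(out)))
    stop("non-finite values in fused effector step", call. = FALSE)

  parents <- list(); tags <- character(0)
  addp <- function(x, tag) {
    if (is.advar(x)) { parents[[length(parents) + 1L]] <<- x
                       tags <<- c(tags, tag) }
  }
  addp(src, "src"); addp(action, "act")
  if (!is.null(fext)) addp(fext, "fext")

  vjp <- function(G) {
    ga1 <- G[, L$ia, drop = FALSE]
    gq1n <- G[, L$iq[1]] + G[, L$icp[1]]
    gq2n <- G[, L$iq[2]] + G[, L$icp[2]]
    gqd1n <- G[, L$iqd[1]] + G[, L$icv[1]]
    gqd2n <- G[, L$iqd[2]] + G[, L$icv[2]]
    glen2 <- G[, L$ipl, drop = FALSE] / l0m
    gvel2 <- G[, L$ipv, drop = FALSE] / l0m
    # records at the new state: dlen/dq = u; du/dq through (I - uu')/len
    gq1n <- gq1n + rowSums(glen2 * g1$ux) +
      rowSums(gvel2 * ((1 - g1$ux^2) * qd1n - g1$ux * g1$uy * qd2n) / g1$len)
    gq2n <- gq2n + rowSums(glen2 * g1$uy) +
      rowSums(gvel2 * ((1 - g1$uy^2) * qd2n - g1$ux * g1$uy * qd1n) / g1$len)
    gqd1n <- gqd1n + rowSums(gvel2 * g1$ux)
    gqd2n <- gqd2n + rowSums(gvel2 * g1$uy)
    gq1np <- gq1n * mq1; gq2np <- gq2n * mq2
    gqd1np <- gqd1n * k1 + dt * gq1np
    gqd2np <- gqd2n * k2 + dt * gq2np
    gq1 <- gq1np; gq2 <- gq2np
    gqd1 <- gqd1np; gqd2 <- gqd2np
    gtau1 <- dt * gqd1np / P$mass; gtau2 <- dt * gqd2np / P$mass
    gfe <- if (is.null(fev)) NULL else cbind(gtau1, gtau2)
    # tau = -sum(u * F): through F and through u(q)
    gF <- -(g0$ux * gtau1 + g0$uy * gtau2)
    gq1 <- gq1 -
      gtau1 * rowSums(Fm * (1 - g0$ux^2) / g0$len) +
      gtau2 * rowSums(Fm * g0$ux * g0$uy / g0$len)
    gq2 <- gq2 +
      gtau1 * rowSums(Fm * g0$ux * g0$uy / g0$len) -
      gtau2 * rowSums(Fm * (1 - g0$uy^2) / g0$len)
    ga1t <- ga1 + gF * fmaxm * mrelu
    ga <- ga1t * ac$d_a
    gact <- ga1t * ac$d_act
    gsrc <- matrix(0, nrow(G), L$K)
    gsrc[, L$ia] <- ga
    gsrc[, L$iq] <- cbind(gq1, gq2)
    gsrc[, L$iqd] <- cbind(gqd1, gqd2)
    all_g <- list(src = gsrc, act = gact, fext = gfe)
    all_g[tags]
  }
  .ad_node(out, parents, vjp)
}

# wrap a fused step node into the effector-state structure used everywhere
.fused_effector_step <- function(eff, state, action, external_force = NULL) {
  fun <- if (eff$skeleton == "two_link") .fused_step_arm else .fused_step_pm
  src <- if (is.null(state$node)) {
    # rebuild the concatenated layout; advar fields are re-joined so
    # gradients keep flowing to them
    if (is.advar(state$q) || is.advar(state$a))
      v_cbind(state$a, state$q, state$qdot, state$cart$pos, state$cart$vel,
              .prop_block(eff, state))
    else .state_concat(eff, state)
  } else state$node
  node <- fun(eff, src, action, external_force)
  m <- eff$n_muscles
  L <- .fused_layout(m)
  list(q = v_cols(node, L$iq), qdot = v_cols(node, L$iqd),
       a = v_cols(node, L$ia), geom = NULL,
       fiber_len = NULL, fiber_vel = NULL, force = NULL,
       cart = list(pos = v_cols(node, L$icp), vel = v_cols(node, L$icv)),
       prop = v_cols(node, c(L$ipl, L$ipv)),
       action = action, node = node)
}

# fused dense sigmoid output layer: action = sigmoid(h %*% Wo + bo) + noise
# (additive noise, when given, shifts the value but not the Jacobian)
.fused_dense_sigmoid <- function(h, Wo, bo, noise = NULL) {
  hv <- ad_value(h); Wv <- ad_value(Wo); bv <- as.numeric(ad_value(bo))
  pre <- hv %*% Wv
  pre <- pre + rep(bv, each = nrow(pre))
  s <- 1 / (1 + exp(-pre))
  out <- if (is.null(noise)) s else s + noise
  parents <- list(); tags <- character(0)
  addp <- function(x, tag) {
    if (is.advar(x)) { parents[[length(parents) + 1L]] <<- x
                       tags <<- c(tags, tag) }
  }
  addp(h, "h"); addp(Wo, "Wo"); addp(bo, "bo")
  vjp <- function(g) {
    ds <- g * s * (1 - s)
    all_g <- list(h = ds %*% t(Wv), Wo = crossprod(hv, ds),
                  bo = matrix(colSums(ds), 1L))
    all_g[tags]
  }
  .ad_node(out, parents, vjp)
}

# fused GRU hidden update (gates r, z, candidate c):
#   r = sig(xWr + hUr + br); z = sig(xWz + hUz + bz)
#   c = tanh(xWc + r * hUc + bc);  h' = z h + (1 - z) c + noise
.fused_gru_hidden <- function(obs, h, Wx, Wh, b, noise = NULL) {
  xv <- ad_value(obs); hv <- ad_value(h)
  Wxv <- ad_value(Wx); Whv <- ad_value(Wh); bv <- as.numeric(ad_value(b))
  n <- ncol(hv)
  ir <- 1:n; iz <- (n + 1L):(2L * n); ic <- (2L * n + 1L):(3L * n)
  px <- xv %*% Wxv
  px <- px + rep(bv, each = nrow(px))
  ph <- hv %*% Whv
  r <- 1 / (1 + exp(-(px[, ir, drop = FALSE] + ph[, ir, drop = FALSE])))
  z <- 1 / (1 + exp(-(px[, iz, drop = FALSE] + ph[, iz, drop = FALSE])))
  cc <- tanh(px[, ic, drop = FALSE] + r * ph[, ic, drop = FALSE])
  hn <- z * hv + (1 - z) * cc
  if (!is.null(noise)) hn <- hn + noise
  parents <- list(); tags <- character(0)
  addp <- function(x, tag) {
    if (is.advar(x)) { parents[[length(parents) + 1L]] <<- x
                       tags <<- c(tags, tag) }
  }
  addp(obs, "obs"); addp(h, "h"); addp(Wx, "Wx"); addp(Wh, "Wh"); addp(b, "b")
  vjp <- function(g) {
    dz <- g * (hv - cc)
    dcpre <- g * (1 - z) * (1 - cc^2)
    dr <- dcpre * ph[, ic, drop = FALSE]
    drpre <- dr * r * (1 - r)
    dzpre <- dz * z * (1 - z)
    dpx <- cbind(drpre, dzpre, dcpre)
    dph <- cbind(drpre, dzpre, dcpre * r)
    all_g <- list(obs = dpx %*% t(Wxv),
                  h = g * z + dph %*% t(Whv),
                  Wx = crossprod(xv, dpx),
                  Wh = crossprod(hv, dph),
                  b = matrix(colSums(dpx), 1L))
    all_g[tags]
  }
  .ad_node(hn, parents, vjp)
}

# fused observation node over the delay buffers. vis_src/prop_src are state
# representations in the fused B x K layout (plain at/before the reset,
# advar after). Noise matrices are drawn by the caller (RNG-order parity
# with the generic route).
.fused_obs_node <- function(env, cond, start_xy, t, vis_src, prop_src,
                            nv = NULL, np = NULL) {
  fb <- env$fb
  m <- env$eff$n_muscles
  L <- .fused_layout(m)
  B <- cond$B
  perceived <- is.finite(cond$go_step) & (t >= cond$go_step + fb$dv_steps)
  gc <- matrix(1 - perceived * 1, B, 1L)
  tgt_in <- ifelse(matrix(perceived, B, 2L), cond$target, start_xy)
  vis <- ad_value(vis_src)[, L$icp, drop = FALSE]
  prop <- ad_value(prop_src)[, c(L$ipl, L$ipv), drop = FALSE]
  if (!is.null(nv)) vis <- vis + nv
  if (!is.null(np)) prop <- prop + np
  val <- cbind(start_xy, tgt_in, gc, vis, prop)
  va <- is.advar(vis_src); pa <- is.advar(prop_src)
  if (!va && !pa) return(val)
  parents <- c(if (va) list(vis_src), if (pa) list(prop_src))
  iv <- 6:7; ip <- 8:(7L + 2L * m)
  vjp <- function(g) {
    out <- list()
    if (va) {
      Z <- matrix(0, B, L$K); Z[, L$icp] <- g[, iv]
      out <- c(out, list(Z))
    }
    if (pa) {
      Z <- matrix(0, B, L$K); Z[, c(L$ipl, L$ipv)] <- g[, ip]
      out <- c(out, list(Z))
    }
    out
  }
  .ad_node(val, parents, vjp)
}

# fused curl-field force from a state node: f = b * (-vy, vx)
.fused_curl_node <- function(state_src, b, L) {
  sv <- ad_value(state_src)
  vx <- sv[, L$icv[1L]]; vy <- sv[, L$icv[2L]]
  val <- cbind(-b * vy, b * vx)
  if (!is.advar(state_src)) return(val)
  B <- nrow(sv)
  vjp <- function(g) {
    Z <- matrix(0, B, L$K)
    Z[, L$icv[1L]] <- b * g[, 2L]
    Z[, L$icv[2L]] <- -b * g[, 1L]
    list(Z)
  }
  .ad_node(val, list(state_src), vjp)
}

# fully fused training rollout: ~5 tape nodes per step. Replicates the
# generic env_reset/env_step semantics (including the RNG call order:
# reset obs noise, then per step hidden noise, action noise, visual noise,
# proprioceptive noise) and is tested for exact agreement with it.
.fused_rollout <- function(env, params, pol_cfg, condition) {
  eff <- env$eff; fb <- env$fb
  m <- eff$n_muscles; n <- pol_cfg$n_units
  L <- .fused_layout(m)
  B <- condition$B; Tn <- env$n_steps
  cond <- condition
  est0 <- effector_reset(eff, joint_position = cond$start_q)
  s0 <- .state_concat(eff, est0)
  start_xy <- ad_value(est0$cart$pos)
  draw <- function(k, sd) if (sd > 0) matrix(stats::rnorm(B * k, 0, sd), B, k)
  src_at <- function(i) if (i <= 0L) s0 else states[[i]]
  states <- vector("list", Tn)
  hs <- vector("list", Tn)
  xstar <- vector("list", Tn)
  stepfun <- if (eff$skeleton == "two_link") .fused_step_arm else .fused_step_pm
  dur <- as.integer(round(0.1 / eff$dt)) # only for bookkeeping parity
  h <- matrix(0, B, n)
  obs <- .fused_obs_node(env, cond, start_xy, 0L, s0, s0,
                         draw(2L, fb$sigma_v), draw(2L * m, fb$sigma_p))
  src <- s0
  for (t in seq_len(Tn)) {
    hn <- .fused_gru_hidden(obs, h, params$Wx, params$Wh, params$b,
                            draw(n, pol_cfg$sigma_h))
    act <- .fused_dense_sigmoid(hn, params$Wo, params$bo,
                                draw(m, fb$sigma_u))
    tprev <- t - 1L
    fext <- NULL
    active <- (cond$pert_mag > 0) & (tprev >= cond$pert_onset) &
      (tprev < cond$pert_onset + cond$pert_dur)
    if (any(active)) {
      mag <- cond$pert_mag * active
      fext <- cbind(mag * cos(cond$pert_dir), mag * sin(cond$pert_dir))
    }
    if (env$curl_b != 0) {
      fc <- .fused_curl_node(src, env$curl_b, L)
      fext <- if (is.null(fext)) fc else fc + fext
    }
    S <- stepfun(eff, src, act, fext)
    states[[t]] <- S; hs[[t]] <- hn
    xstar[[t]] <- desired_position(cond, start_xy, t)
    src <- S; h <- hn
    obs <- .fused_obs_node(env, cond, start_xy, t,
                           src_at(t - fb$dv_steps), src_at(t - fb$dp_steps),
                           draw(2L, fb$sigma_v), draw(2L * m, fb$sigma_p))
  }
  SS <- v_rbind(states)
  H <- v_rbind(hs)
  Hprev <- v_rbind(c(list(matrix(0, B, n)), hs[-Tn]))
  records <- list(X = v_cols(SS, L$icp), Xs = do.call(rbind, xstar),
                  U = v_cols(SS, L$ia), H = H, Hd = H - Hprev)
  list(records = records,
       final = list(pos = ad_value(src)[, L$icp, drop = FALSE],
                    vel = ad_value(src)[, L$icv, drop = FALSE]))
}
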