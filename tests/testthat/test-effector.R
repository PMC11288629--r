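test_that("reset places the effector consistently and samples uniformly", {
  eff <- RigidTendonArm26()
  st <- effector_reset(eff, joint_position = c(deg(45), deg(90)))
  fk <- forward_kinematics(joint_state(c(deg(45), deg(90))), eff$P)
  expect_equal(ad_value(st$cart$pos), ad_value(fk$pos))
  expect_equal(ad_value(st$qdot), matrix(0, 1, 2))
  expect_true(all(st$a == eff$rest_activation))
  expect_error(effector_reset(eff, joint_position = c(-1, 0)), "limits")
  # determinism
  s1 <- effector_reset(eff, batch_size = 5, seed = 99)
  s2 <- effector_reset(eff, batch_size = 5, seed = 99)
  expect_identical(s1$q, s2$q)
  # uniformity over the joint box
  sN <- effector_reset(eff, batch_size = 10000, seed = 100)
  lo <- eff$P$q_lower; hi <- eff$P$q_upper
  for (j in 1:2) {
    x <- sN$q[, j]
    expect_gte(min(x), lo[j]); expect_lte(max(x), hi[j])
    ks <- suppressWarnings(stats::ks.test(x, "punif", lo[j], hi[j]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("a posture with all fibers at or below slack is a fixed point", {
  eff <- RigidTendonArm26(rest_activation = 0)
  q0 <- c(0.9, 1.3)
  st <- effector_reset(eff, joint_position = q0)
  # verify the premise before asserting the consequence
  fiber <- (ad_value(st$geom$len) - eff$lt) / eff$l0
  expect_true(all(fiber <= eff$mc$normalized_slack_length))
  st2 <- st
  for (i in 1:20) st2 <- effector_step(eff, st2, matrix(0, 1, 6))
  expect_equal(st2$q, st$q, tolerance = 1e-12)
  expect_equal(st2$qdot, st$qdot, tolerance = 1e-12)
})

test_that("extreme postures drift passively under null input", {
  eff <- RigidTendonArm26("paths", rest_activation = 0)
  st <- effector_reset(eff, joint_position = c(deg(135), deg(155)))
  p0 <- ad_value(st$cart$pos)
  for (i in 1:20) st <- effector_step(eff, st, matrix(0, 1, 6))
  expect_gt(sqrt(sum((ad_value(st$cart$pos) - p0)^2)), 1e-3)
})

test_that("cartesian state equals forward kinematics after every step", {
  eff <- RigidTendonArm26()
  st <- effector_reset(eff, batch_size = 3, seed = 4)
  set.seed(4)
  for (i in 1:10) {
    st <- effector_step(eff, st, matrix(runif(18), 3, 6))
    fk <- forward_kinematics(list(q = st$q, qdot = st$qdot), eff$P)
    expect_lt(max(abs(ad_value(st$cart$pos) - ad_value(fk$pos))), 1e-12)
    expect_lt(max(abs(ad_value(st$cart$vel) - ad_value(fk$vel))), 1e-12)
    # rigid-tendon consistency of the recorded muscle state
    expect_equal(ad_value(st$fiber_len),
                 pmax(sweep(sweep(ad_value(st$geom$len), 2, as.numeric(eff$lt)),
                            2, as.numeric(eff$l0), "/"), 0.01),
                 tolerance = 1e-12)
  }
})

test_that("external endpoint force maps through the Jacobian transpose", {
  eff <- RigidTendonArm26(rest_activation = 0)
  q0 <- c(0.9, 1.3) # passive-free posture so only the external force acts
  st <- effector_reset(eff, joint_position = q0)
  fext <- matrix(c(2, -1), 1)
  st1 <- effector_step(eff, st, matrix(0, 1, 6), external_force = fext)
  J <- matrix(ad_value(two_link_jacobian(matrix(q0, 1), eff$P)), 2, 2, byrow = TRUE)
  tau <- t(J) %*% t(fext)
  qdd_expect <- as.numeric(two_link_dynamics(joint_state(q0),
                                             matrix(tau, 1), eff$P))
  expect_equal(as.numeric(st1$qdot) / eff$dt, qdd_expect, tolerance = 1e-9)
})

test_that("joint limits clamp position and zero outward velocity", {
  eff <- RigidTendonArm26(rest_activation = 0)
  st <- effector_reset(eff, joint_position = c(0.01, 1))
  st$qdot <- matrix(c(-5, 0), 1) # driving the shoulder into its stop
  st1 <- effector_step(eff, st, matrix(0, 1, 6))
  expect_gte(st1$q[1, 1], eff$P$q_lower[1])
  expect_equal(st1$qdot[1, 1], 0)
})

test_that("NaN inputs fail loudly with the offending stage named", {
  eff <- RigidTendonArm26()
  st <- effector_reset(eff, joint_position = c(1, 1))
  expect_error(effector_step(eff, st, matrix(NaN, 1, 6)), "muscle force")
})

test_that("point-mass ReLU effector at rest is unchanged by zero action", {
  eff <- ReluPointMass24()
  st <- effector_reset(eff, joint_position = c(0.5, -0.2))
  st1 <- effector_step(eff, st, matrix(0, 1, 4))
  expect_identical(st1$q, st$q)
  expect_identical(st1$qdot, st$qdot)
  expect_identical(ad_value(st1$a), ad_value(st$a))
})

test_that("fused and primitive engines agree on values and gradients", {
  for (mk in list(function() RandomReach(RigidTendonArm26(), horizon = 0.1),
                  function() RandomReach(ReluPointMass24(), horizon = 0.1,
                                         perturb = TRUE))) {
    env <- mk()
    eff <- env$eff
    pc <- policy_config(8, env$obs_size, eff$n_muscles)
    pp <- init_policy(pc, seed = 31)
    set.seed(32)
    cond <- sample_condition(env, 3)
    lc <- loss_config()
    out <- lapply(c("auto", "primitive"), function(engine) {
      set.seed(33)
      ad_begin()
      p_ad <- lapply(pp, ad_var)
      ro <- rollout(env, p_ad, pc, cond, engine = engine)
      loss <- total_loss(ro$records, as.numeric(eff$fmax), p_ad$Wx, lc)
      ad_backward(loss)
      g <- lapply(p_ad, ad_grad)
      ad_end()
      list(l = ad_value(loss)[1], g = g)
    })
    expect_equal(out[[1]]$l, out[[2]]$l, tolerance = 1e-14)
    for (k in names(out[[1]]$g))
      expect_lt(max(abs(out[[1]]$g[[k]] - out[[2]]$g[[k]])), 1e-12)
  }
})
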