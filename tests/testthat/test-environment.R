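test_that("curl field force is orthogonal, scaled, counter-clockwise", {
  expect_equal(curl_field_force(c(1, 0), b = 8), c(0, 8))
  expect_equal(curl_field_force(c(0.3, -0.7), b = 0), c(0, 0))
  set.seed(41)
  for (i in 1:20) {
    v <- rnorm(2)
    f <- curl_field_force(v, b = 8)
    expect_equal(sum(f * v), 0)
    expect_equal(sqrt(sum(f^2)), 8 * sqrt(sum(v^2)))
  }
})

test_that("condition sampling matches the stated training distribution", {
  env <- RandomReach(ReluPointMass24(), horizon = 0.8, perturb = TRUE)
  set.seed(42)
  cond <- sample_condition(env, 10000)
  catch <- !is.finite(cond$go_step)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.5) / 10000
  expect_gt(mean(catch), ci[1]); expect_lt(mean(catch), ci[2])
  # perturbed non-catch trials: magnitude U(0, 4)
  mag_nc <- cond$pert_mag[!catch & cond$pert_mag > 0]
  expect_lte(max(mag_nc), 4)
  se <- 4 / sqrt(12) / sqrt(length(mag_nc))
  expect_lt(abs(mean(mag_nc) - 2), 3 * se)
  # catch trials widen the distribution to U(0, 8)
  mag_c <- cond$pert_mag[catch & cond$pert_mag > 0]
  expect_lte(max(mag_c), 8)
  expect_gt(max(mag_c), 4.5)
  # go-cue times uniform over the window
  gt <- cond$go_step[!catch]
  expect_gte(min(gt), 0); expect_lte(max(gt), env$n_steps - 1)
  # desired position on catch trials stays at the start for the whole window
  i_catch <- which(catch)[1]
  start_xy <- cond$start_q[i_catch, , drop = FALSE]
  for (t in c(0L, 40L, 79L)) {
    ds <- desired_position(cond, cond$start_q, t)
    expect_equal(ds[i_catch, ], start_xy[1, ])
  }
  # and switches instantly (undelayed) on go trials
  i_go <- which(!catch & cond$go_step > 5)[1]
  ds_pre <- desired_position(cond, cond$start_q, as.integer(cond$go_step[i_go]) - 1L)
  ds_post <- desired_position(cond, cond$start_q, as.integer(cond$go_step[i_go]))
  expect_equal(ds_pre[i_go, ], cond$start_q[i_go, ])
  expect_equal(ds_post[i_go, ], cond$target[i_go, ])
})

test_that("episodes truncate at the horizon and refuse further steps", {
  env <- RandomReach(ReluPointMass24(), horizon = 1.0)
  rs <- env_reset(env, batch_size = 2, seed = 43)
  es <- rs$state
  for (t in 1:100) {
    out <- env_step(env, es, matrix(0.1, 2, 4))
    es <- out$state
  }
  expect_true(out$truncated)
  expect_false(out$terminated)
  expect_equal(out$reward, 0)
  expect_equal(es$t, 100L)
  expect_error(env_step(env, es, matrix(0, 2, 4)), "truncated")
})

test_that("visual feedback lags the instantaneous state by exactly the delay", {
  eff <- ReluPointMass24()
  env <- RandomReach(eff, horizon = 0.8)
  expect_equal(env$fb$dv_steps, 5L) # 50 ms at dt = 10 ms
  expect_equal(env$fb$dp_steps, 2L)
  set.seed(44)
  cond <- sample_condition(env, 1)
  rs <- env_reset(env, condition = cond)
  es <- rs$state
  true_pos <- list(ad_value(es$eff_state$cart$pos))
  obs_vis <- list()
  set.seed(45)
  for (t in 1:60) {
    out <- env_step(env, es, matrix(runif(4, 0, 0.4), 1, 4))
    es <- out$state
    true_pos[[t + 1]] <- ad_value(out$info$cart$pos)
    obs_vis[[t]] <- ad_value(out$observation)[, 6:7]
  }
  # info is instantaneous; the visual block replays it 5 steps late
  for (t in 6:60)
    expect_equal(obs_vis[[t]], as.numeric(true_pos[[t - 5 + 1]]), tolerance = 1e-12)
  # before the delay has elapsed the buffer pads with the reset state
  for (t in 1:4)
    expect_equal(obs_vis[[t]], as.numeric(true_pos[[1]]), tolerance = 1e-12)
  # the lagged agreement is exclusive: no other lag in 0..8 reproduces the
  # trajectory, so the delay is exactly 5 steps
  err_at_lag <- vapply(0:8, function(l) {
    idx <- (l + 1):60
    max(vapply(idx, function(t)
      max(abs(obs_vis[[t]] - as.numeric(true_pos[[t - l + 1]]))), numeric(1)))
  }, numeric(1))
  expect_equal(which(err_at_lag < 1e-12) - 1L, 5L)
})

test_that("go-cue reaches the network only after the visual delay", {
  eff <- ReluPointMass24()
  env <- CentreOutReach(eff, horizon = 0.5, go_time = 0.1)
  cond <- sample_condition(env, 1, target_idx = 3L)
  rs <- env_reset(env, condition = cond)
  es <- rs$state
  gc <- c(); tgt <- list()
  for (t in 1:30) {
    out <- env_step(env, es, matrix(0, 1, 4))
    es <- out$state
    ob <- ad_value(out$observation)
    gc[t] <- ob[, 5]
    tgt[[t]] <- ob[, 3:4]
  }
  # the visual block at step t replays the state at t - dv, so the go-cue
  # event at step 10 is first visible at step 15
  go_perceived <- cond$go_step[1] + env$fb$dv_steps # step 15
  expect_true(all(gc[seq_len(go_perceived - 1)] == 1))
  expect_true(all(gc[go_perceived:30] == 0))
  for (t in seq_len(go_perceived - 1))
    expect_equal(tgt[[t]], as.numeric(es$start_xy))
  expect_equal(tgt[[go_perceived]], cond$target[1, ])
})

test_that("observation noise is reproducible from the seed", {
  env <- RandomReach(ReluPointMass24(), horizon = 0.2,
                     fb = feedback_config(sigma_v = 0.01, sigma_p = 0.005))
  run <- function() {
    rs <- env_reset(env, batch_size = 2, seed = 46)
    es <- rs$state
    obs <- list(rs$observation)
    for (t in 1:20) {
      out <- env_step(env, es, matrix(0.2, 2, 4))
      es <- out$state
      obs[[t + 1]] <- out$observation
    }
    obs
  }
  o1 <- run(); o2 <- run()
  for (t in seq_along(o1)) expect_identical(o1[[t]], o2[[t]])
  # noise-free channels (task inputs) are untouched, feedback is perturbed
  rs <- env_reset(env, batch_size = 1, seed = 47)
  out <- env_step(env, rs$state, matrix(0, 1, 4))
  expect_false(isTRUE(all.equal(ad_value(out$observation)[, 6:7],
                                as.numeric(ad_value(out$info$cart$pos)))))
})

test_that("perturbation force integrates to magnitude x duration x direction", {
  eff <- ReluPointMass24()
  env <- RandomReach(eff, horizon = 0.5)
  cond <- trial_conditions(start_q = matrix(c(0, 0), 1),
                           target = matrix(c(0.1, 0), 1),
                           go_step = 0,
                           pert_mag = 3, pert_dir = pi / 3,
                           pert_onset = 10L, pert_dur = 10L)
  rs <- env_reset(env, condition = cond)
  es <- rs$state
  total <- c(0, 0)
  for (t in 1:50) {
    f <- diffeffector:::.external_force(env, es)
    if (!is.null(f)) total <- total + as.numeric(f) * eff$dt
    out <- env_step(env, es, matrix(0, 1, 4))
    es <- out$state
  }
  expect_equal(total, 3 * 0.1 * c(cos(pi / 3), sin(pi / 3)), tolerance = 1e-12)
})

test_that("zero-noise episodes replay bit-identically", {
  env <- RandomReach(RigidTendonArm26(), horizon = 0.3)
  set.seed(48)
  cond <- sample_condition(env, 2)
  run <- function() {
    rs <- env_reset(env, condition = cond)
    es <- rs$state
    traj <- list()
    for (t in 1:30) {
      out <- env_step(env, es, matrix(0.1 + 0.01 * t, 2, 6))
      es <- out$state
      traj[[t]] <- ad_value(out$info$cart$pos)
    }
    traj
  }
  expect_identical(run(), run())
})
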