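test_that("PMD regression recovers designed tuning", {
  n_dir <- 24L
  dirs <- 2 * pi * (0:(n_dir - 1)) / n_dir
  Tn <- 40L; go <- 10L
  # unit 1: one-hot for direction 7; unit 2: cosine tuned at 135 deg;
  # unit 3: constant across directions
  Hs <- lapply(seq_len(n_dir), function(d) {
    H <- matrix(0, Tn, 3L)
    if (d == 7L) H[(go + 1):(go + 15), 1L] <- 1
    H[(go + 1):(go + 15), 2L] <- 1 + cos(dirs[d] - deg(135))
    H[, 3L] <- 0.4
    H
  })
  res <- compute_pmd(Hs, go, dirs)
  expect_equal(res$pmd[1L], 7L)
  expect_equal(max(res$beta_norm[, 1L]), 1)
  expect_equal(sum(res$beta_norm[, 1L] > 0.5), 1L)
  expect_equal(dirs[res$pmd[2L]], deg(135))
  # constant unit: flat profile, tie broken to the lowest index
  expect_true(all(res$beta_norm[, 3L] == 0))
  expect_equal(res$pmd[3L], 1L)
  expect_equal(sum(res$hist), 3L)
  expect_error(compute_pmd(Hs[1:10], go, dirs), "fewer")
})

test_that("Rayleigh test separates uniform from axially concentrated angles", {
  n_dir <- 24L
  dirs <- 2 * pi * (0:(n_dir - 1)) / n_dir
  flat <- rep(10, n_dir)
  expect_gt(rayleigh_test(dirs, flat, double = TRUE)$p.value, 0.05)
  # bimodal mass at 135 and 315 degrees: invisible to the plain test,
  # caught by angle doubling
  bimodal <- rep(1, n_dir)
  bimodal[c(10, 22)] <- 40 # 135 deg and 315 deg at 15-deg spacing
  expect_gt(rayleigh_test(dirs, bimodal, double = FALSE)$p.value, 0.05)
  expect_lt(rayleigh_test(dirs, bimodal, double = TRUE)$p.value, 1e-4)
})

test_that("passive drift is nonnegative, centre-quiet, and vanishes without passive force", {
  res <- passive_drift_map(grid_n = 7L, duration = 0.1)
  expect_true(all(res$drift >= 0))
  centre <- res$drift[4, 4]
  boundary <- max(res$drift[c(1, 7), ], res$drift[, c(1, 7)])
  expect_lt(centre, boundary)
  # disabling the passive curve (slack at infinity) removes all drift
  eff_off <- RigidTendonArm26("paths",
                              muscle_config = muscle_params(1, normalized_slack_length = Inf),
                              rest_activation = 0)
  res0 <- passive_drift_map(eff_off, grid_n = 5L, duration = 0.1)
  expect_true(all(res0$drift == 0))
})

test_that("lateral deviation is signed perpendicular excursion", {
  start <- c(0, 0); target <- c(1, 0)
  traj <- cbind(seq(0, 1, length.out = 11), c(0, 0.1, 0.2, 0.1, 0, -0.05, 0, 0, 0, 0, 0))
  expect_equal(lateral_deviation(traj, start, target), 0.2)
  # mirrored path flips the sign
  traj2 <- traj; traj2[, 2] <- -traj2[, 2]
  expect_equal(lateral_deviation(traj2, start, target), -0.2)
})

test_that("protocols are deterministic given config and seed", {
  r1 <- run_curl_field_protocol(seed = 71, batches_init = 2, batches_adapt = 1,
                                batch_size = 4)
  r2 <- run_curl_field_protocol(seed = 71, batches_init = 2, batches_adapt = 1,
                                batch_size = 4)
  expect_identical(r1$lateral, r2$lateral)
  expect_identical(r1$trajectories$adapted_curl, r2$trajectories$adapted_curl)
  expect_equal(dim(r1$trajectories$naive_null), c(100, 8, 2))
})

test_that("perturbation protocol: identical commands before the perturbation", {
  res <- run_perturbation_protocol(perturbed_training = TRUE, seed = 72,
                                   batches = 2, batch_size = 4,
                                   n_units = 16,
                                   reach_mags = c(0, -6), postural_mags = 6)
  unpert <- res$reach[[1]]; pert <- res$reach[[2]]
  onset <- 10L + 5L + 7L # go + visual delay + 70 ms
  for (t in seq_len(onset))
    expect_identical(unpert$activations[[t]], pert$activations[[t]])
  # and they diverge afterwards (force changes the feedback)
  later <- vapply(seq(onset + 10L, 80L), function(t)
    max(abs(unpert$activations[[t]] - pert$activations[[t]])), numeric(1))
  expect_gt(max(later), 0)
  expect_equal(length(res$postural), 1L)
  expect_true(all(is.finite(res$postural[[1]]$final_dist)))
})

test_that("PMD protocol runs end-to-end and is deterministic at toy scale", {
  r1 <- run_pmd_protocol("pointmass", n_networks = 1, seed = 73,
                         batches = 2, batch_size = 4, n_units = 12)
  r2 <- run_pmd_protocol("pointmass", n_networks = 1, seed = 73,
                         batches = 2, batch_size = 4, n_units = 12)
  expect_identical(r1$hist, r2$hist)
  expect_equal(sum(r1$hist), 12)
  expect_equal(length(r1$directions), 24L)
})

test_that("configs and exports round-trip", {
  cfg <- list(effector = "RigidTendonArm26", geometry = "paths",
              muscle = list(normalized_slack_length = 1.5))
  eff <- effector_from_config(cfg)
  expect_equal(eff$geometry, "paths")
  expect_equal(eff$mc$normalized_slack_length, 1.5)
  env <- env_from_config(eff, list(task = "centre_out", horizon = 1,
                                   curl_b = 8,
                                   feedback = list(sigma_v = 0.01)))
  expect_equal(env$curl_b, 8)
  expect_equal(env$n_steps, 100L)
  expect_equal(env$fb$sigma_v, 0.01)
  tf <- tempfile(fileext = ".csv")
  write_trajectories_csv(array(rnorm(20 * 3 * 2), c(20, 3, 2)), tf)
  df <- utils::read.csv(tf)
  expect_equal(nrow(df), 60L)
  unlink(tf)
  cs <- muscle_curve_samples(muscle_params(500))
  expect_true(all(cs$FL <= 1 & cs$FL > 0))
  expect_true(all(cs$FP >= 0))
  expect_equal(cs$FV[which.min(abs(cs$norm_velocity))], 1, tolerance = 0.02)
})
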