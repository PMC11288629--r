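#' @title Replication protocols
#'
#' @description
#' Scripted versions of the package's replication studies:
#'
#' * **Curl-field adaptation** ([run_curl_field_protocol()]): train a
#'   50-unit GRU on delayed random reaches with a fixed 100-ms go-cue
#'   (1-s trials), test 8 centre-out reaches in a null and a
#'   counter-clockwise curl field (b = 8), resume training *in* the curl
#'   field on the test configuration (50% catch trials), and re-test.
#'   Adaptation shows as reduced lateral deviation under the curl field
#'   and an opposite-signed after-effect in the null field.
#' * **Perturbation generalization** ([run_perturbation_protocol()]):
#'   train with (or without) random 100-ms endpoint perturbations, then
#'   probe reaching and postural control with within- and
#'   out-of-distribution force magnitudes.
#' * **Preferential movement direction** ([run_pmd_protocol()],
#'   [compute_pmd()]): train several networks per effector on the general
#'   reach design, run 24-target centre-out tests, regress each unit's
#'   150-ms post-go-cue activity on reach direction, and build the PMD
#'   histogram per effector. Arm-like geometry concentrates PMDs around
#'   the 135/315-degree axis; the point-mass does not.
#' * **Passive drift map** ([passive_drift_map()]): endpoint drift under
#'   null input over a grid of start postures, caused solely by passive
#'   muscle force beyond the slack length.
#'
#' Every protocol takes a `scale` argument: `"ci"` runs the reduced sizes
#' used by the automated tests; `"full"` uses the full published batch
#' counts (desk-scale, minutes to hours).
#'
#' @name experiments_replication
NULL

.scale_batches <- function(scale, ci, full) {
  switch(scale, ci = ci, full = full,
         stop("unknown scale: ", scale, call. = FALSE))
}

# simulate an effector open-loop (fixed action) for n steps; batch states
.simulate_null <- function(eff, state, n_steps, action = NULL) {
  B <- nrow(ad_value(state$q))
  if (is.null(action)) action <- matrix(0, B, eff$n_muscles)
  for (t in seq_len(n_steps)) state <- effector_step(eff, state, action)
  state
}

#' Passive-drift map over the joint space
#'
#' Resets the arm on an evenly spaced grid of joint configurations with
#' zero activation, simulates `duration` seconds with null input, and
#' records the endpoint displacement of every start. Only passive muscle
#' stretch beyond the slack length can move the arm, so the drift is
#' negligible at the centre of the joint space and grows toward its
#' edges.
#'
#' @param eff arm effector (defaults to the path-geometry arm)
#' @param grid_n grid resolution per joint (default 21)
#' @param duration simulated time (s, default 0.2)
#' @return list with `q1`, `q2` (grid axes), `drift` (`grid_n x grid_n`
#'   displacement magnitudes, m), `start`, `end` (endpoint positions)
#' @export
passive_drift_map <- function(eff = RigidTendonArm26("paths"),
                              grid_n = 21L, duration = 0.2) {
  stopifnot(eff$muscle_type == "hill")
  q1s <- seq(eff$P$q_lower[1], eff$P$q_upper[1], length.out = grid_n)
  q2s <- seq(eff$P$q_lower[2], eff$P$q_upper[2], length.out = grid_n)
  grid <- as.matrix(expand.grid(q1 = q1s, q2 = q2s))
  st <- effector_reset(eff, joint_position = grid)
  st$a[] <- 0 # null input: no activation at all
  p0 <- ad_value(st$cart$pos)
  stn <- .simulate_null(eff, st, as.integer(round(duration / eff$dt)))
  p1 <- ad_value(stn$cart$pos)
  drift <- sqrt(rowSums((p1 - p0)^2))
  list(q1 = q1s, q2 = q2s,
       drift = matrix(drift, grid_n, grid_n),
       start = p0, end = p1)
}

# positions over time from generic-rollout records: T x B x 2 array
.traj_array <- function(records) {
  Tn <- length(records$x)
  B <- nrow(ad_value(records$x[[1L]]))
  arr <- array(NA_real_, c(Tn, B, 2L))
  for (t in seq_len(Tn)) arr[t, , ] <- ad_value(records$x[[t]])
  arr
}

#' Signed lateral deviation of a trajectory from the straight reach line
#'
#' @param traj `T x 2` matrix of endpoint positions
#' @param start,target 2-vectors defining the reach line
#' @return the signed maximal perpendicular deviation (m); positive to
#'   the left of the start-to-target direction
#' @export
lateral_deviation <- function(traj, start, target) {
  d <- target - start
  u <- d / sqrt(sum(d^2))
  rel <- sweep(traj, 2L, start)
  perp <- rel[, 2L] * u[1L] - rel[, 1L] * u[2L]
  perp[which.max(abs(perp))]
}

#' Curl-field adaptation protocol
#'
#' @param seed integer seed
#' @param scale `"ci"` (reduced batch counts) or `"full"` (the published
#'   7680 + 768 batches of 64)
#' @param n_units GRU size (default 50)
#' @param batches_init,batches_adapt batch counts, overriding `scale`
#' @param batch_size trials per batch
#' @param lr Adam learning rate
#' @param b curl-field strength (N s/m)
#' @return list with `trajectories` (named list `naive_null`,
#'   `naive_curl`, `adapted_null`, `adapted_curl`; each `T x 8 x 2`),
#'   `lateral` (per-condition signed lateral deviations), `targets`,
#'   `start`, `params` (trained parameters), `loss` curves
#' @export
run_curl_field_protocol <- function(seed = 1L, scale = c("ci", "full"),
                                    n_units = 50L,
                                    batches_init = NULL, batches_adapt = NULL,
                                    batch_size = NULL, lr = NULL, b = 8) {
  scale <- match.arg(scale)
  if (is.null(batches_init)) batches_init <- .scale_batches(scale, 260L, 7680L)
  if (is.null(batches_adapt)) batches_adapt <- .scale_batches(scale, 64L, 768L)
  if (is.null(batch_size)) batch_size <- .scale_batches(scale, 32L, 64L)
  # scaled runs need a faster optimizer to converge in few batches; the
  # learning rate is tooling, not part of the modelled science
  if (is.null(lr)) lr <- .scale_batches(scale, 3e-3, 1e-3)
  eff <- RigidTendonArm26()
  # general training design, go-cue fixed at 100 ms, 1-s trials
  tr_env <- task_env(eff, "random", horizon = 1, random_go = FALSE,
                     go_time = 0.1, catch_p = 0.5)
  pc <- policy_config(n_units, tr_env$obs_size, eff$n_muscles)
  set.seed(seed)
  params <- init_policy(pc)
  fit1 <- train(tr_env, params, pc, loss_config(), batches = batches_init,
                batch_size = batch_size, lr = lr)
  test_once <- function(params, curl_b) {
    tenv <- task_env(eff, "centre_out", horizon = 1, catch_p = 0,
                     go_time = 0.1, curl_b = curl_b)
    cond <- sample_condition(tenv, 8L, target_idx = 1:8)
    ro <- rollout(tenv, params, pc, cond)
    list(traj = .traj_array(ro$records), cond = cond)
  }
  t_nn <- test_once(fit1$params, 0)
  t_nc <- test_once(fit1$params, b)
  # adaptation: resume training in the curl field on the test layout
  ad_env <- task_env(eff, "centre_out", horizon = 1, catch_p = 0.5,
                     go_time = 0.1, curl_b = b)
  fit2 <- train(ad_env, fit1$params, pc, loss_config(),
                batches = batches_adapt, batch_size = batch_size, lr = lr)
  t_an <- test_once(fit2$params, 0)
  t_ac <- test_once(fit2$params, b)
  start <- t_nn$cond$start_q
  start_xy <- ad_value(.cartesian(eff, matrix(start[1, ], 1), matrix(0, 1, 2))$pos)
  lat <- function(tt) vapply(seq_len(8L), function(i)
    lateral_deviation(tt$traj[, i, ], start_xy[1, ], tt$cond$target[i, ]),
    numeric(1L))
  list(trajectories = list(naive_null = t_nn$traj, naive_curl = t_nc$traj,
                           adapted_null = t_an$traj, adapted_curl = t_ac$traj),
       lateral = list(naive_null = lat(t_nn), naive_curl = lat(t_nc),
                      adapted_null = lat(t_an), adapted_curl = lat(t_ac)),
       targets = t_nn$cond$target, start = start_xy,
       params = fit2$params, params_naive = fit1$params,
       loss = list(initial = fit1$loss, adaptation = fit2$loss))
}

#' Perturbation-generalization protocol
#'
#' Trains on the general reach design (with or without random endpoint
#' perturbations and with excitation/hidden noise), then probes (a) a
#' centre-out reach task with orthogonal perturbations 70 ms after the
#' go-cue is perceived and (b) a postural task with cardinal-direction
#' perturbations at 170 ms plus the visual delay.
#'
#' @param perturbed_training logical: expose the network to random
#'   perturbations during training
#' @param seed integer seed
#' @param scale `"ci"` or `"full"` (27,000 batches of 1024)
#' @param n_units GRU size (default 110)
#' @param lr Adam learning rate (scale-dependent default)
#' @param batches,batch_size training sizes, overriding `scale`
#' @param reach_mags,postural_mags perturbation magnitudes probed (N)
#' @return list with `reach` and `postural` per-magnitude results (final
#'   distances, trajectories, activations), plus trained `params`
#' @export
run_perturbation_protocol <- function(perturbed_training = TRUE, seed = 1L,
                                      scale = c("ci", "full"),
                                      n_units = 110L, lr = NULL,
                                      batches = NULL, batch_size = NULL,
                                      reach_mags = c(-6, -3, 0, 3, 6),
                                      postural_mags = c(-12, -6, 6, 12)) {
  scale <- match.arg(scale)
  if (is.null(batches)) batches <- .scale_batches(scale, 200L, 27000L)
  if (is.null(batch_size)) batch_size <- .scale_batches(scale, 32L, 1024L)
  if (is.null(lr)) lr <- .scale_batches(scale, 3e-3, 1e-3)
  eff <- RigidTendonArm26()
  fb <- feedback_config(sigma_u = 1e-2, sigma_h = 1e-3)
  tr_env <- task_env(eff, "random", horizon = 0.8, fb = fb,
                     perturb = perturbed_training, catch_p = 0.5)
  pc <- policy_config(n_units, tr_env$obs_size, eff$n_muscles,
                      sigma_h = fb$sigma_h)
  set.seed(seed)
  params <- init_policy(pc)
  fit <- train(tr_env, params, pc, loss_config(), batches = batches,
               batch_size = batch_size, lr = lr)
  dt <- eff$dt
  dv <- fb$dv_steps
  fb_test <- feedback_config() # noise-free probes
  reach <- lapply(reach_mags, function(mag) {
    # shared RNG across magnitudes: probe rollouts of the same reach are
    # identical until the perturbation arrives
    set.seed(seed * 100L + 17L)
    tenv <- task_env(eff, "centre_out", horizon = 0.8, catch_p = 0,
                     go_time = 0.1, fb = fb_test)
    cond <- sample_condition(tenv, 8L, target_idx = 1:8)
    if (mag != 0) {
      ang <- 2 * pi * (0:7) / 8
      cond$pert_mag <- rep(abs(mag), 8L)
      cond$pert_dir <- ang + sign(mag) * pi / 2 # orthogonal to the reach
      cond$pert_onset <- rep(cond$go_step[1L] + dv + 7L, 8L)
      cond$pert_dur <- rep(as.integer(round(0.1 / dt)), 8L)
    }
    ro <- rollout(tenv, fit$params, pc, cond)
    fin <- ro$env_state$eff_state
    list(magnitude = mag,
         final_dist = sqrt(rowSums((ad_value(fin$cart$pos) - cond$target)^2)),
         traj = .traj_array(ro$records),
         activations = lapply(ro$records$u, ad_value))
  })
  postural <- lapply(postural_mags, function(mag) {
    set.seed(seed * 100L + 18L)
    tenv <- task_env(eff, "postural", horizon = 0.8, fb = fb_test)
    cond <- sample_condition(tenv, 4L)
    cond$pert_mag <- rep(abs(mag), 4L)
    cond$pert_dir <- c(0, pi / 2, pi, 3 * pi / 2) + (mag < 0) * pi
    cond$pert_onset <- rep(as.integer(round(0.17 / dt)) + dv, 4L)
    cond$pert_dur <- rep(as.integer(round(0.1 / dt)), 4L)
    ro <- rollout(tenv, fit$params, pc, cond)
    fin <- ro$env_state$eff_state
    list(magnitude = mag,
         final_dist = sqrt(rowSums((ad_value(fin$cart$pos) - cond$target)^2)),
         traj = .traj_array(ro$records))
  })
  list(reach = reach, postural = postural, params = fit$params,
       pol_cfg = pc, loss = fit$loss, perturbed_training = perturbed_training)
}

#' Preferential movement direction of recurrent units
#'
#' Averages each unit's hidden activity in a 150-ms window starting when
#' the go-cue reaches the network (go-cue time plus the visual delay),
#' regresses the per-direction averages on a one-hot direction design
#' (whose least-squares coefficients are exactly those averages),
#' normalizes the absolute coefficients to `[0, 1]` per unit, and takes
#' the argmax as the unit's PMD. Ties break toward the lowest direction
#' index.
#'
#' @param hidden_trajectories list over directions of `T x n` hidden
#'   activity matrices (one trial per direction)
#' @param go_cue_perceived_step 0-based step at which the go-cue reaches
#'   the network
#' @param directions direction angles (rad), one per trajectory
#' @param window_ms averaging window (ms, default 150)
#' @param dt timestep (s)
#' @return list with `beta` (directions x units averages), `beta_norm`
#'   (normalized to `[0, 1]` per unit), `pmd` (per-unit direction index),
#'   `hist` (unit counts per direction), `directions`
#' @export
compute_pmd <- function(hidden_trajectories, go_cue_perceived_step,
                        directions, window_ms = 150, dt = 0.01) {
  D <- length(directions)
  if (length(hidden_trajectories) < D)
    stop("fewer trajectories than directions", call. = FALSE)
  wlen <- as.integer(round(window_ms / 1000 / dt))
  i0 <- go_cue_perceived_step + 1L # 1-based row of the perception step
  beta <- t(vapply(hidden_trajectories, function(H) {
    idx <- i0:min(i0 + wlen - 1L, nrow(H))
    colMeans(H[idx, , drop = FALSE])
  }, numeric(ncol(hidden_trajectories[[1L]]))))
  ab <- abs(beta)
  rng <- apply(ab, 2L, function(x) {
    s <- max(x) - min(x)
    if (s == 0) rep(0, length(x)) else (x - min(x)) / s
  })
  beta_norm <- matrix(rng, nrow = D)
  pmd <- apply(beta_norm, 2L, which.max) # ties -> lowest index
  hist <- tabulate(pmd, nbins = D)
  list(beta = beta, beta_norm = beta_norm, pmd = pmd, hist = hist,
       directions = directions)
}

#' Rayleigh test of circular uniformity (optionally on doubled angles)
#'
#' Doubling the angles makes the test sensitive to bimodal (axial)
#' concentrations such as the 135/315-degree PMD axis.
#'
#' @param angles angles (rad)
#' @param weights nonnegative weights (e.g. histogram counts)
#' @param double double the angles before testing
#' @return list with `R` (resultant length), `n` (effective count),
#'   `statistic` (`n R^2`) and `p.value`
#' @export
rayleigh_test <- function(angles, weights = NULL, double = FALSE) {
  if (is.null(weights)) weights <- rep(1, length(angles))
  stopifnot(length(weights) == length(angles), all(weights >= 0))
  a <- if (double) 2 * angles else angles
  n <- sum(weights)
  C <- sum(weights * cos(a)) / n
  S <- sum(weights * sin(a)) / n
  R <- sqrt(C^2 + S^2)
  z <- n * R^2
  # Zar's approximation to the Rayleigh p-value
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (R * n)^2)) - (1 + 2 * n))
  list(R = R, n = n, statistic = z, p.value = min(max(p, 0), 1))
}

#' PMD replication protocol
#'
#' Trains `n_networks` GRU policies per effector on the general reach
#' design (target radius 0 in the loss), runs a 24-target centre-out
#' test, and accumulates the PMD histogram averaged over networks.
#'
#' @param effector `"arm26"` or `"pointmass"`
#' @param n_networks networks to train (the full study uses 8)
#' @param seed integer seed
#' @param scale `"ci"` or `"full"` (38,400 batches of 64)
#' @param n_units GRU size (default 90; 50 at CI scale)
#' @param lr Adam learning rate (scale-dependent default)
#' @param batches,batch_size training sizes, overriding `scale`
#' @param n_targets number of reach directions (default 24)
#' @return list with `hist` (average unit count per direction),
#'   `directions`, per-network `pmd` results, and the doubled-angle
#'   Rayleigh test of the averaged histogram
#' @export
run_pmd_protocol <- function(effector = c("arm26", "pointmass"),
                             n_networks = 8L, seed = 1L,
                             scale = c("ci", "full"),
                             n_units = 90L, lr = NULL,
                             batches = NULL, batch_size = NULL,
                             n_targets = 24L) {
  effector <- match.arg(effector)
  scale <- match.arg(scale)
  if (is.null(batches)) batches <- .scale_batches(scale, 220L, 38400L)
  if (is.null(batch_size)) batch_size <- .scale_batches(scale, 32L, 64L)
  if (is.null(lr)) lr <- .scale_batches(scale, 3e-3, 1e-3)
  if (scale == "ci" && missing(n_units)) n_units <- 50L
  eff <- if (effector == "arm26") RigidTendonArm26() else ReluPointMass24()
  tr_env <- task_env(eff, "random", horizon = 0.8, catch_p = 0.5)
  pc <- policy_config(n_units, tr_env$obs_size, eff$n_muscles)
  tenv <- task_env(eff, "centre_out", horizon = 0.8, catch_p = 0,
                   go_time = 0.1, n_targets = n_targets)
  go_perceived <- as.integer(round(tenv$go_time / eff$dt)) + tenv$fb$dv_steps
  directions <- 2 * pi * (seq_len(n_targets) - 1L) / n_targets
  nets <- vector("list", n_networks)
  hist_acc <- numeric(n_targets)
  for (k in seq_len(n_networks)) {
    set.seed(seed * 1000L + k)
    params <- init_policy(pc)
    fit <- train(tr_env, params, pc, loss_config(r = 0), batches = batches,
                 batch_size = batch_size, lr = lr)
    cond <- sample_condition(tenv, n_targets, target_idx = seq_len(n_targets))
    ro <- rollout(tenv, fit$params, pc, cond)
    # records$h[[t]] is (directions x units); rearrange per direction
    Hs <- lapply(seq_len(n_targets), function(d)
      t(vapply(ro$records$h, function(h) ad_value(h)[d, ], numeric(n_units))))
    res <- compute_pmd(Hs, go_perceived, directions, dt = eff$dt)
    nets[[k]] <- res
    hist_acc <- hist_acc + res$hist
  }
  hist_avg <- hist_acc / n_networks
  list(hist = hist_avg, directions = directions, networks = nets,
       rayleigh = rayleigh_test(directions, weights = hist_avg, double = TRUE),
       effector = effector)
}
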