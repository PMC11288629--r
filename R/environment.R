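#' @title Task environments: delayed noisy feedback around the effector
#'
#' @description
#' Environments wrap an effector in the standard agent-environment step
#' contract (`reset()` then repeated `step(action)` returning observation,
#' reward, terminated, truncated, info). The observation concatenates, in
#' this fixed order:
#'
#' 1. task inputs (5): start position x, y; target-input x, y; go-cue
#'    channel (1 before the go-cue is *perceived*, 0 after);
#' 2. visual feedback (2): endpoint position delayed by `delta_v` with
#'    Gaussian noise `sigma_v`;
#' 3. proprioceptive feedback (2m): normalized muscle lengths and
#'    velocities delayed by `delta_p` with noise `sigma_p`.
#'
#' The go-cue is a visual event: the desired position used by the loss
#' switches to the target immediately at the go-cue, but the target-input
#' and go-cue channels seen by the network switch only `delta_v` later.
#' Catch trials (probability `catch_p` during training) provide no go-cue,
#' so the task reduces to holding the start. Optional external forces are
#' a velocity-dependent curl field `f = b * (-ydot, xdot)` and/or a
#' 100-ms mechanical perturbation of random magnitude and orientation.
#' Reward is identically 0: learning uses the differentiable loss, the
#' reward slot exists for interface compatibility.
#'
#' @name task_environments
NULL

#' Feedback delay/noise configuration
#'
#' @param delta_p proprioceptive delay (s), multiple of `dt`; default 20 ms
#' @param delta_v visual delay (s), multiple of `dt`; default 50 ms
#' @param sigma_h hidden-activity noise SD (used by the policy)
#' @param sigma_u action noise SD
#' @param sigma_p proprioceptive noise SD
#' @param sigma_v visual noise SD
#' @param dt timestep (s)
#' @return object of class `feedback_config`
#' @export
feedback_config <- function(delta_p = 0.02, delta_v = 0.05,
                            sigma_h = 0, sigma_u = 0,
                            sigma_p = 0, sigma_v = 0, dt = 0.01) {
  stopifnot(delta_p >= 0, delta_v >= 0,
            sigma_h >= 0, sigma_u >= 0, sigma_p >= 0, sigma_v >= 0)
  dp <- delta_p / dt; dv <- delta_v / dt
  if (abs(dp - round(dp)) > 1e-9 || abs(dv - round(dv)) > 1e-9)
    stop("delays must be integer multiples of dt", call. = FALSE)
  structure(list(delta_p = delta_p, delta_v = delta_v,
                 dp_steps = as.integer(round(dp)),
                 dv_steps = as.integer(round(dv)),
                 sigma_h = sigma_h, sigma_u = sigma_u,
                 sigma_p = sigma_p, sigma_v = sigma_v, dt = dt),
            class = "feedback_config")
}

#' Curl-field endpoint force
#'
#' `f = b * (-ydot, xdot)`: counter-clockwise, proportional to speed and
#' always orthogonal to the endpoint velocity. `b = 0` is the null field.
#'
#' @param endpoint_velocity `B x 2` endpoint velocity (m/s) or a 2-vector
#' @param b field strength (N s / m)
#' @return force, same shape as the input (N)
#' @export
curl_field_force <- function(endpoint_velocity, b = 8) {
  vec <- !is.matrix(endpoint_velocity) && !is.advar(endpoint_velocity)
  v <- if (vec) matrix(endpoint_velocity, nrow = 1L) else endpoint_velocity
  f <- v_cbind(-b * v_cols(v, 2L), b * v_cols(v, 1L))
  if (vec) as.numeric(ad_value(f)) else f
}

#' Construct a batch of trial conditions
#'
#' @param start_q `B x dof` start coordinates
#' @param target `B x 2` cartesian target positions (m)
#' @param go_step integer vector of go-cue steps (`Inf` = catch trial)
#' @param pert_mag,pert_dir,pert_onset,pert_dur perturbation magnitude (N),
#'   direction (rad), onset step and duration in steps (0 magnitude = no
#'   perturbation)
#' @return object of class `trial_conditions`
#' @export
trial_conditions <- function(start_q, target, go_step,
                             pert_mag = NULL, pert_dir = NULL,
                             pert_onset = NULL, pert_dur = NULL) {
  B <- nrow(start_q)
  if (is.null(pert_mag)) pert_mag <- rep(0, B)
  if (is.null(pert_dir)) pert_dir <- rep(0, B)
  if (is.null(pert_onset)) pert_onset <- rep(0L, B)
  if (is.null(pert_dur)) pert_dur <- rep(0L, B)
  stopifnot(all(pert_mag >= 0), nrow(target) == B,
            length(go_step) == B)
  structure(list(start_q = start_q, target = target, go_step = go_step,
                 pert_mag = pert_mag, pert_dir = pert_dir,
                 pert_onset = pert_onset, pert_dur = pert_dur, B = B),
            class = "trial_conditions")
}

#' Task environment specification
#'
#' Presets: [RandomReach()] (the training distribution: uniform start and
#' target over joint space, uniform go-cue, 50% catch trials, optional
#' random perturbations), [CentreOutReach()] (fixed start, radial targets,
#' fixed go-cue), [DelayedReach()], [Postural()].
#'
#' @param eff [effector()]
#' @param task `"random"`, `"centre_out"` or `"postural"`
#' @param horizon simulation duration (s)
#' @param fb [feedback_config()]
#' @param curl_b curl-field strength (N s/m); 0 = null field
#' @param perturb logical: sample random 100-ms endpoint perturbations
#'   (magnitude U(0, 4) N, or U(0, 8) N on catch trials)
#' @param catch_p catch-trial probability
#' @param n_targets number of radial targets (centre-out)
#' @param target_distance radial target distance (m)
#' @param go_time fixed go-cue time (s), used by centre-out and by the
#'   random task when `random_go = FALSE`
#' @param random_go draw the go-cue time uniformly over the window
#'   (random task); `FALSE` fixes it at `go_time`
#' @param start_q fixed start coordinates (centre-out / postural); default
#'   shoulder 45 deg, elbow 90 deg for the arm, (0, 0) for the point-mass
#' @return object of class `task_env`
#' @export
task_env <- function(eff, task = c("random", "centre_out", "postural"),
                     horizon = 0.8, fb = feedback_config(),
                     curl_b = 0, perturb = FALSE, catch_p = 0.5,
                     n_targets = 8L, target_distance = 0.1, go_time = 0.1,
                     random_go = TRUE, start_q = NULL) {
  task <- match.arg(task)
  if (is.null(start_q))
    start_q <- if (eff$skeleton == "two_link") c(pi / 4, pi / 2) else c(0, 0)
  n_steps <- as.integer(round(horizon / eff$dt))
  structure(list(eff = eff, task = task, horizon = horizon,
                 n_steps = n_steps, fb = fb, curl_b = curl_b,
                 perturb = perturb, catch_p = catch_p,
                 n_targets = as.integer(n_targets),
                 target_distance = target_distance,
                 go_time = go_time, random_go = random_go, start_q = start_q,
                 obs_size = 5L + 2L + 2L * eff$n_muscles),
            class = "task_env")
}

#' @rdname task_env
#' @param ... passed to [task_env()]
#' @export
RandomReach <- function(eff, ...) task_env(eff, task = "random", ...)

#' @rdname task_env
#' @export
DelayedReach <- function(eff, ...) task_env(eff, task = "random", ...)

#' @rdname task_env
#' @export
CentreOutReach <- function(eff, ...)
  task_env(eff, task = "centre_out", catch_p = 0, ...)

#' @rdname task_env
#' @export
Postural <- function(eff, ...) task_env(eff, task = "postural", ...)

#' Sample a batch of trial conditions for an environment
#'
#' Random task: start and target drawn uniformly over the joint-limit box
#' (targets mapped through forward kinematics), go-cue uniform over the
#' simulation window, catch trials with probability `catch_p`;
#' perturbations (if enabled) in 50% of trials, 100 ms long, orientation
#' uniform, onset uniform, magnitude U(0, 4) N (U(0, 8) N on catch
#' trials). Centre-out: fixed start, target index uniform among the
#' radial targets, fixed go-cue. Postural: catch trial (no go-cue) from
#' the fixed start.
#'
#' @param env [task_env()]
#' @param batch_size number of trials
#' @param target_idx optional integer vector of target indices
#'   (centre-out), e.g. `1:8` for one reach per target
#' @return [trial_conditions()]
#' @export
sample_condition <- function(env, batch_size = 1L, target_idx = NULL) {
  eff <- env$eff; B <- as.integer(batch_size)
  lo <- eff$P$q_lower; hi <- eff$P$q_upper
  dof <- eff$dof
  n_steps <- env$n_steps
  if (env$task == "random") {
    start_q <- matrix(stats::runif(B * dof, rep(lo, each = B), rep(hi, each = B)),
                      B, dof)
    tgt_q <- matrix(stats::runif(B * dof, rep(lo, each = B), rep(hi, each = B)),
                    B, dof)
    target <- ad_value(.cartesian(eff, tgt_q, matrix(0, B, dof))$pos)
    catch <- stats::runif(B) < env$catch_p
    go_step <- if (env$random_go)
      ifelse(catch, Inf, sample.int(n_steps, B, replace = TRUE) - 1L)
    else ifelse(catch, Inf, as.integer(round(env$go_time / eff$dt)))
  } else {
    start_q <- matrix(env$start_q, B, dof, byrow = TRUE)
    start_xy <- ad_value(.cartesian(eff, start_q, matrix(0, B, dof))$pos)
    if (env$task == "postural") {
      target <- start_xy
      go_step <- rep(Inf, B)
    } else {
      if (is.null(target_idx))
        target_idx <- sample.int(env$n_targets, B, replace = TRUE)
      ang <- 2 * pi * (target_idx - 1L) / env$n_targets
      target <- start_xy + env$target_distance * cbind(cos(ang), sin(ang))
      catch <- stats::runif(B) < env$catch_p
      go_step <- ifelse(catch, Inf, as.integer(round(env$go_time / eff$dt)))
    }
  }
  pm <- rep(0, B); pd <- rep(0, B); po <- rep(0L, B); pl <- rep(0L, B)
  if (isTRUE(env$perturb)) {
    hit <- stats::runif(B) < 0.5
    is_catch <- !is.finite(go_step)
    hi_mag <- ifelse(is_catch, 8, 4)
    pm <- ifelse(hit, stats::runif(B, 0, hi_mag), 0)
    pd <- stats::runif(B, 0, 2 * pi)
    dur <- as.integer(round(0.1 / eff$dt))
    po <- sample.int(max(n_steps - dur, 1L), B, replace = TRUE) - 1L
    pl <- ifelse(hit, dur, 0L)
  }
  trial_conditions(start_q, target, go_step, pm, pd, po, pl)
}

# observation assembly; returns B x obs_size (advar if any feedback is)
.make_obs <- function(env, es) {
  fb <- env$fb; cond <- es$cond; t <- es$t; B <- cond$B
  # visual block: delayed endpoint + noise
  iv <- max(t - fb$dv_steps, 0L) + 1L
  vis <- es$buf_vis[[iv]]
  if (fb$sigma_v > 0)
    vis <- vis + matrix(stats::rnorm(B * 2L, 0, fb$sigma_v), B, 2L)
  # proprioceptive block
  ip <- max(t - fb$dp_steps, 0L) + 1L
  prop <- es$buf_prop[[ip]]
  if (fb$sigma_p > 0)
    prop <- prop + matrix(stats::rnorm(B * ncol(ad_value(prop)), 0, fb$sigma_p),
                          B, ncol(ad_value(prop)))
  # task inputs: go is perceived Delta_v after it occurs
  perceived <- is.finite(cond$go_step) & (t >= cond$go_step + fb$dv_steps)
  gc <- matrix(1 - perceived * 1, B, 1L)
  tgt_in <- ifelse(matrix(perceived, B, 2L), cond$target, es$start_xy)
  v_cbind(es$start_xy, tgt_in, gc, vis, prop)
}

#' Assemble the observation vector for the current step
#'
#' Exposed mainly for inspection and tests; [env_reset()] and [env_step()]
#' call it internally.
#' @param env [task_env()]
#' @param env_state environment state
#' @return `B x (5 + 2 + 2m)` observation
#' @export
make_observation <- function(env, env_state) .make_obs(env, env_state)

# normalized proprioceptive block from an effector state; fused steps
# provide it precomputed
.prop_block <- function(eff, state) {
  if (!is.null(state$prop)) return(state$prop)
  scale <- 1 / eff$l0
  v_cbind(v_mul(state$geom$len, scale), v_mul(state$geom$vel, scale))
}

#' Reset a task environment
#'
#' @param env [task_env()]
#' @param batch_size number of parallel trials
#' @param condition optional [trial_conditions()]; sampled if NULL
#' @param seed optional integer seed (conditions and all trial noise)
#' @return list with `state` (environment state), `observation`, `info`
#'   (instantaneous effector state)
#' @export
env_reset <- function(env, batch_size = 1L, condition = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(condition)) condition <- sample_condition(env, batch_size)
  eff <- env$eff
  est <- effector_reset(eff, joint_position = condition$start_q)
  start_xy <- ad_value(est$cart$pos)
  es <- list(t = 0L, cond = condition, eff_state = est,
             start_xy = start_xy,
             buf_vis = list(est$cart$pos),
             buf_prop = list(.prop_block(eff, est)),
             truncated = FALSE)
  obs <- .make_obs(env, es)
  list(state = es, observation = obs, info = est)
}

# external force at step t for each trial: perturbation window + curl
.external_force <- function(env, es) {
  cond <- es$cond; t <- es$t; B <- cond$B
  f <- NULL
  active <- (cond$pert_mag > 0) & (t >= cond$pert_onset) &
    (t < cond$pert_onset + cond$pert_dur)
  if (any(active)) {
    mag <- cond$pert_mag * active
    f <- cbind(mag * cos(cond$pert_dir), mag * sin(cond$pert_dir))
  }
  if (env$curl_b != 0) {
    fc <- curl_field_force(es$eff_state$cart$vel, env$curl_b)
    f <- if (is.null(f)) fc else fc + f
  }
  f
}

#' Advance a task environment by one step
#'
#' Applies action noise, composes external forces (perturbation window,
#' curl field), steps the effector, appends to the delay buffers, and
#' returns the standard quintuple.
#'
#' @param env [task_env()]
#' @param env_state environment state from [env_reset()]/previous step
#' @param action `B x m` action matrix
#' @param engine autodiff route, passed through to [effector_step()]
#' @return list with `state`, `observation`, `reward` (always 0),
#'   `terminated`, `truncated`, `info` (instantaneous effector state)
#' @export
env_step <- function(env, env_state, action, engine = c("auto", "primitive")) {
  engine <- match.arg(engine)
  es <- env_state
  if (isTRUE(es$truncated))
    stop("step() called on a truncated episode; reset first", call. = FALSE)
  eff <- env$eff; fb <- env$fb; B <- es$cond$B
  if (fb$sigma_u > 0)
    action <- action +
      matrix(stats::rnorm(B * eff$n_muscles, 0, fb$sigma_u), B, eff$n_muscles)
  f_ext <- .external_force(env, es)
  est <- effector_step(eff, es$eff_state, action, external_force = f_ext,
                       engine = engine)
  es$eff_state <- est
  es$t <- es$t + 1L
  es$buf_vis[[es$t + 1L]] <- est$cart$pos
  es$buf_prop[[es$t + 1L]] <- .prop_block(eff, est)
  es$truncated <- es$t >= env$n_steps
  obs <- .make_obs(env, es)
  list(state = es, observation = obs, reward = 0,
       terminated = FALSE, truncated = es$truncated, info = est)
}

#' Instantaneous desired position at a step
#'
#' The loss target `x*`: the start position until the go-cue occurs
#' (instantaneously, not delayed), the target afterwards; the start
#' throughout on catch trials.
#' @param cond [trial_conditions()]
#' @param start_xy `B x 2` start positions
#' @param t step index
#' @return `B x 2` desired positions
#' @export
desired_position <- function(cond, start_xy, t) {
  gone <- is.finite(cond$go_step) & (t >= cond$go_step)
  ifelse(matrix(gone, cond$B, 2L), cond$target, start_xy)
}
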