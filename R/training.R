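#' @title Training by backpropagation through the effector
#'
#' @description
#' A training iteration samples a batch of trial conditions, rolls the
#' GRU policy out through the environment with every operation recorded
#' on the autodiff tape -- including the muscle dynamics, geometry and
#' skeleton physics -- computes the composite loss, backpropagates
#' through time *and* through the effector, and applies an Adam update
#' with global gradient-norm clipping. Optimizer choice, learning rate
#' and clipping threshold are not part of the modelled science; they
#' default to community-standard values (Adam, 1e-3, clip 1.0) and are
#' configurable.
#'
#' @name training
NULL

# roll the policy through the environment; all differentiable quantities
# are advars when a tape is active. Returns records for the loss plus the
# final env state.
.rollout <- function(env, params, pol_cfg, condition, engine = "auto") {
  if (engine == "auto" && is.advar(params$Wx) && .fused_capable(env$eff))
    return(.fused_rollout(env, params, pol_cfg, condition))
  B <- condition$B
  n <- pol_cfg$n_units
  rs <- env_reset(env, condition = condition)
  es <- rs$state; obs <- rs$observation
  h <- matrix(0, B, n)
  rec <- list(x = vector("list", env$n_steps),
              xstar = vector("list", env$n_steps),
              u = vector("list", env$n_steps),
              h = vector("list", env$n_steps),
              hdot = vector("list", env$n_steps),
              action = vector("list", env$n_steps))
  for (t in seq_len(env$n_steps)) {
    pf <- policy_forward(params, obs, h, pol_cfg$sigma_h, engine = engine)
    stp <- env_step(env, es, pf$action, engine = engine)
    es <- stp$state; obs <- stp$observation
    rec$x[[t]] <- es$eff_state$cart$pos
    rec$xstar[[t]] <- desired_position(condition, es$start_xy, es$t)
    rec$u[[t]] <- es$eff_state$a
    rec$h[[t]] <- pf$hidden
    rec$hdot[[t]] <- pf$hidden - h
    rec$action[[t]] <- pf$action
    h <- pf$hidden
  }
  list(records = rec, env_state = es)
}

#' Roll out a policy in an environment (no gradients)
#'
#' @param env [task_env()]
#' @param params policy parameters ([init_policy()])
#' @param pol_cfg [policy_config()]
#' @param condition [trial_conditions()]
#' @param engine autodiff route (`"auto"` or `"primitive"`)
#' @return list with `records` (per-step positions, desired positions,
#'   activations, hidden states, actions) and `env_state`
#' @export
rollout <- function(env, params, pol_cfg, condition, engine = "auto") {
  .rollout(env, params, pol_cfg, condition, engine = engine)
}

.adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, clip = 1.0) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1L))))
  if (is.finite(clip) && gn > clip) grads <- lapply(grads, function(g) g * (clip / gn))
  st$t <- st$t + 1L
  corr1 <- 1 - beta1^st$t; corr2 <- 1 - beta2^st$t
  for (k in names(params)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grads[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (st$m[[k]] / corr1) / (sqrt(st$v[[k]] / corr2) + eps)
  }
  list(params = params, state = st, grad_norm = gn)
}

#' Train a GRU policy through a differentiable environment
#'
#' @param env [task_env()]
#' @param params initial policy parameters ([init_policy()])
#' @param pol_cfg [policy_config()]
#' @param loss_cfg [loss_config()]
#' @param batches number of training batches
#' @param batch_size trials per batch
#' @param lr Adam learning rate
#' @param clip global gradient-norm clip
#' @param seed integer seed controlling condition sampling and all noise
#' @param verbose print the running loss every `verbose` batches (0 = quiet)
#' @return list with `params` (trained), `loss` (per-batch loss curve),
#'   `grad_norm` (per-batch gradient norms)
#' @export
train <- function(env, params, pol_cfg, loss_cfg = loss_config(),
                  batches = 100L, batch_size = 32L, lr = 1e-3, clip = 1.0,
                  seed = NULL, verbose = 0L, engine = "auto") {
  if (!is.null(seed)) set.seed(seed)
  opt <- .adam_init(params)
  loss_curve <- numeric(batches)
  gn_curve <- numeric(batches)
  f <- as.numeric(env$eff$fmax)
  for (bi in seq_len(batches)) {
    cond <- sample_condition(env, batch_size)
    ad_begin()
    p_ad <- lapply(params, ad_var)
    ro <- .rollout(env, p_ad, pol_cfg, cond, engine = engine)
    loss <- total_loss(ro$records, f, p_ad$Wx, loss_cfg)
    lv <- ad_value(loss)[1L]
    if (!is.finite(lv)) {
      ad_end()
      stop("NaN/Inf loss at batch ", bi, call. = FALSE)
    }
    ad_backward(loss)
    grads <- lapply(p_ad, function(p) {
      g <- ad_grad(p)
      if (is.null(g)) p$v * 0 else g
    })
    ad_end()
    upd <- .adam_step(params, grads, opt, lr = lr, clip = clip)
    params <- upd$params; opt <- upd$state
    loss_curve[bi] <- lv
    gn_curve[bi] <- upd$grad_norm
    if (verbose > 0L && bi %% verbose == 0L)
      message(sprintf("batch %d/%d  loss %.5f", bi, batches, lv))
  }
  list(params = params, loss = loss_curve, grad_norm = gn_curve)
}

#' Gradient of the final endpoint position with respect to all actions
#'
#' Runs a rollout in which the action at every timestep is an independent
#' leaf node (no policy), then backpropagates the summed final endpoint
#' position through the full physics. Used to verify end-to-end
#' differentiability of the effector.
#'
#' @param env [task_env()]
#' @param condition [trial_conditions()] for a single trial (B = 1)
#' @param actions `T x m` matrix of actions (one row per step)
#' @param engine autodiff route (`"auto"` or `"primitive"`)
#' @return list with `gradients` (`T x m` matrix of
#'   `d(sum(final_pos))/d(action)`), `final_pos` (2-vector)
#' @export
endpoint_gradient <- function(env, condition, actions, engine = "auto") {
  stopifnot(condition$B == 1L, nrow(actions) == env$n_steps)
  ad_begin()
  on.exit(ad_end())
  rs <- env_reset(env, condition = condition)
  es <- rs$state
  acts <- vector("list", env$n_steps)
  for (t in seq_len(env$n_steps)) {
    acts[[t]] <- ad_var(actions[t, , drop = FALSE])
    stp <- env_step(env, es, acts[[t]], engine = engine)
    es <- stp$state
  }
  target <- v_sum(es$eff_state$cart$pos)
  ad_backward(target)
  g <- t(vapply(acts, function(a) {
    gr <- ad_grad(a)
    if (is.null(gr)) rep(0, env$eff$n_muscles) else as.numeric(gr)
  }, numeric(env$eff$n_muscles)))
  list(gradients = g, final_pos = as.numeric(ad_value(es$eff_state$cart$pos)))
}
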