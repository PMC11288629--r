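#' @title GRU policy network
#'
#' @description
#' A one-layer gated recurrent unit (GRU) policy with sigmoid gate
#' activations and a tanh candidate activation, fully connected to a
#' sigmoid output layer with one node per muscle. Initialization follows
#' the package's training studies: Glorot-uniform input kernel,
#' orthogonal recurrent kernel, zero GRU biases, output kernel
#' N(0, 0.003^2) and output bias -5 (so initial actions are
#' `sigmoid(-5) ~ 0.0067`, keeping the effector quiescent at the start of
#' training). Gaussian noise of SD `sigma_h` can be injected into the
#' hidden state each step.
#'
#' @name policy_and_training
NULL

#' Policy configuration
#'
#' @param n_units hidden units n
#' @param input_size observation length (5 + 2 + 2m)
#' @param output_size number of muscles m
#' @param sigma_h hidden-noise SD
#' @param output_kernel_sd SD of the output-kernel initializer
#' @param output_bias initial output bias
#' @return object of class `policy_config`
#' @export
policy_config <- function(n_units, input_size, output_size,
                          sigma_h = 0, output_kernel_sd = 0.003,
                          output_bias = -5) {
  stopifnot(n_units >= 1, input_size >= 1, output_size >= 1)
  structure(as.list(environment()), class = "policy_config")
}

# orthogonal n x n matrix from a seeded QR factorization
.orthogonal_init <- function(n) {
  A <- matrix(stats::rnorm(n * n), n, n)
  qr_ <- qr(A)
  Q <- qr.Q(qr_)
  # fix signs so the distribution is Haar-uniform
  d <- sign(diag(qr.R(qr_)))
  Q * rep(d, each = n)
}

#' Initialize GRU policy parameters
#'
#' @param config [policy_config()]
#' @param seed optional integer seed
#' @return list of parameter matrices: `Wx` (input kernel, I x 3n, gate
#'   order reset/update/candidate), `Wh` (recurrent kernel, n x 3n,
#'   block-orthogonal), `b` (1 x 3n, zeros), `Wo` (n x m), `bo` (1 x m)
#' @export
init_policy <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  I <- config$input_size; n <- config$n_units; m <- config$output_size
  limit <- sqrt(6 / (I + n))
  Wx <- matrix(stats::runif(I * 3L * n, -limit, limit), I, 3L * n)
  Wh <- cbind(.orthogonal_init(n), .orthogonal_init(n), .orthogonal_init(n))
  b <- matrix(0, 1L, 3L * n)
  Wo <- matrix(stats::rnorm(n * m, 0, config$output_kernel_sd), n, m)
  bo <- matrix(config$output_bias, 1L, m)
  list(Wx = Wx, Wh = Wh, b = b, Wo = Wo, bo = bo)
}

#' One forward step of the GRU policy
#'
#' @param params parameter list from [init_policy()] (plain matrices or
#'   `advar` nodes during training)
#' @param observation `B x I` observation
#' @param hidden `B x n` hidden state
#' @param sigma_h hidden-noise SD (0 disables noise)
#' @param engine `"auto"` uses fused autodiff kernels during recording;
#'   `"primitive"` forces the elementary-op route (gradient oracle)
#' @return list with `action` (`B x m`, in (0, 1)) and `hidden` (`B x n`)
#' @export
policy_forward <- function(params, observation, hidden, sigma_h = 0,
                           engine = c("auto", "primitive")) {
  engine <- match.arg(engine)
  n <- ncol(ad_value(hidden))
  if (engine == "auto" &&
      (is.advar(params$Wx) || is.advar(observation) || is.advar(hidden))) {
    noise <- if (sigma_h > 0) {
      B <- nrow(ad_value(hidden))
      matrix(stats::rnorm(B * n, 0, sigma_h), B, n)
    }
    h_new <- .fused_gru_hidden(observation, hidden, params$Wx, params$Wh,
                               params$b, noise)
    action <- .fused_dense_sigmoid(h_new, params$Wo, params$bo)
    return(list(action = action, hidden = h_new))
  }
  pre_x <- v_mm(observation, params$Wx)
  pre_h <- v_mm(hidden, params$Wh)
  ir <- 1:n; iz <- (n + 1L):(2L * n); ic <- (2L * n + 1L):(3L * n)
  bx <- params$b
  r <- v_sigmoid(v_add(v_cols(pre_x, ir) + v_cols(pre_h, ir), v_cols(bx, ir)))
  z <- v_sigmoid(v_add(v_cols(pre_x, iz) + v_cols(pre_h, iz), v_cols(bx, iz)))
  cand <- tanh(v_add(v_cols(pre_x, ic) + r * v_cols(pre_h, ic), v_cols(bx, ic)))
  h_new <- z * hidden + (1 - z) * cand
  if (sigma_h > 0) {
    B <- nrow(ad_value(h_new))
    h_new <- h_new + matrix(stats::rnorm(B * n, 0, sigma_h), B, n)
  }
  action <- v_sigmoid(v_add(v_mm(h_new, params$Wo), params$bo))
  list(action = action, hidden = h_new)
}

#' Loss configuration
#'
#' Weights of the composite training loss
#' `mean_t(alpha*Lp + beta*Lm + gamma*Lh) + lambda*||Wx||`:
#' positional L1 cost outside the target radius, muscle-activation cost
#' scaled by muscle strength, hidden-activity cost with a derivative term
#' discouraging oscillations, and a kernel-norm penalty.
#'
#' @param alpha positional weight (default 2)
#' @param beta muscle weight (default 5)
#' @param gamma hidden weight (default 0.1)
#' @param kappa hidden-derivative weight (default 0.05)
#' @param lambda kernel penalty (default 1e-5)
#' @param r target radius (m, default 0.01)
#' @param muscle_loss_form `"scaled_sum"` for `((u.f)/||f||^2)^2` (default)
#'   or `"sum_squares"` for `sum((u*f)^2)/||f||^2`
#' @return object of class `loss_config`
#' @export
loss_config <- function(alpha = 2, beta = 5, gamma = 0.1, kappa = 0.05,
                        lambda = 1e-5, r = 0.01,
                        muscle_loss_form = c("scaled_sum", "sum_squares")) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, kappa >= 0, lambda >= 0, r >= 0)
  muscle_loss_form <- match.arg(muscle_loss_form)
  structure(as.list(environment()), class = "loss_config")
}

#' Positional loss
#'
#' 0 inside the target radius (Euclidean), otherwise the L1 distance.
#' @param x `B x 2` position
#' @param xstar `B x 2` desired position
#' @param r target radius (m)
#' @return `B x 1` loss
#' @export
positional_loss <- function(x, xstar, r = 0.01) {
  d <- x - xstar
  l2 <- sqrt(v_rowsums(d * d) + 1e-16) # eps guards d(ad)sqrt at 0
  l1 <- v_rowsums(abs(d))
  inside <- (ad_value(l2) < r) * 1
  v_where(inside, 0 * l1, l1)
}

#' Muscle activation loss
#'
#' Activation cost scaled by muscle strength; the default form is
#' `((u' f) / ||f||_2^2)^2`, the alternative `sum((u*f)^2) / ||f||_2^2`.
#' @param u `B x m` muscle activations
#' @param f length-m maximum isometric forces (or `1 x m` matrix)
#' @param form `"scaled_sum"` or `"sum_squares"`
#' @return `B x 1` loss
#' @export
muscle_loss <- function(u, f, form = c("scaled_sum", "sum_squares")) {
  form <- match.arg(form)
  f <- matrix(as.numeric(ad_value(f)), 1L)
  if (ncol(ad_value(u)) != ncol(f)) stop("length mismatch", call. = FALSE)
  stopifnot(all(f > 0))
  f2 <- sum(f^2)
  if (form == "scaled_sum") {
    s <- v_rowsums(v_mul(u, f)) / f2
    s * s
  } else {
    uf <- v_mul(u, f)
    v_rowsums(uf * uf) / f2
  }
}

#' Hidden-activity loss
#'
#' `h'h/n + kappa * hdot'hdot/n`; `hdot` is the per-step difference of the
#' hidden state (not divided by dt; the kappa coefficient absorbs the
#' constant).
#' @param h `B x n` hidden activity
#' @param hdot `B x n` per-step hidden difference
#' @param kappa derivative weight
#' @return `B x 1` loss
#' @export
hidden_loss <- function(h, hdot, kappa = 0.05) {
  n <- ncol(ad_value(h))
  v_rowsums(h * h) / n + kappa * (v_rowsums(hdot * hdot) / n)
}

#' Total rollout loss
#'
#' Time-mean of the instantaneous composite loss plus the kernel penalty
#' `lambda * ||Wx||_F` on the GRU input kernel.
#'
#' @param records list with per-step lists `x` (`B x 2` positions),
#'   `xstar`, `u` (`B x m` activations), `h`, `hdot` (`B x n`)
#' @param f max-isometric-force vector (length m)
#' @param Wx GRU input kernel (matrix or `advar`)
#' @param cfg [loss_config()]
#' @return `1 x 1` scalar loss (advar when inputs are recorded)
#' @export
total_loss <- function(records, f, Wx, cfg = loss_config()) {
  if (!is.null(records$X)) {
    # already time-stacked (fused rollout)
    X <- records$X; Xs <- records$Xs; U <- records$U
    H <- records$H; Hd <- records$Hd
    if (nrow(ad_value(X)) == 0L) stop("empty trajectory", call. = FALSE)
    lt <- cfg$alpha * v_mean(positional_loss(X, Xs, cfg$r)) +
      cfg$beta * v_mean(muscle_loss(U, f, cfg$muscle_loss_form)) +
      cfg$gamma * v_mean(hidden_loss(H, Hd, cfg$kappa))
    return(lt + cfg$lambda * sqrt(v_sum(Wx * Wx)))
  }
  Tn <- length(records$x)
  if (Tn == 0L) stop("empty trajectory", call. = FALSE)
  # stack time along rows: the time-mean of per-step batch means equals
  # one mean over the (B*T)-row stack since every step has the same batch
  X <- v_rbind(records$x)
  Xs <- v_rbind(records$xstar)
  U <- v_rbind(records$u)
  H <- v_rbind(records$h)
  Hd <- v_rbind(records$hdot)
  lt <- cfg$alpha * v_mean(positional_loss(X, Xs, cfg$r)) +
    cfg$beta * v_mean(muscle_loss(U, f, cfg$muscle_loss_form)) +
    cfg$gamma * v_mean(hidden_loss(H, Hd, cfg$kappa))
  lt + cfg$lambda * sqrt(v_sum(Wx * Wx))
}
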