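pc <- policy_config(n_units = 24, input_size = 19, output_size = 6)

test_that("initialization follows the stated scheme", {
  pp <- init_policy(pc, seed = 51)
  n <- pc$n_units
  # recurrent kernel: three orthogonal blocks
  for (blk in 1:3) {
    Q <- pp$Wh[, ((blk - 1) * n + 1):(blk * n)]
    expect_lt(max(abs(crossprod(Q) - diag(n))), 1e-6)
  }
  expect_true(all(pp$b == 0))
  expect_true(all(pp$bo == -5))
  expect_lt(stats::sd(pp$Wo), 0.01) # tight output kernel
  # zero input, zero hidden: action ~ sigmoid(-5) per muscle
  out <- policy_forward(pp, matrix(0, 1, 19), matrix(0, 1, n))
  expect_equal(as.numeric(ad_value(out$action)),
               rep(1 / (1 + exp(5)), 6), tolerance = 1e-3)
  expect_lt(max(ad_value(out$action)), 0.01)
  # reproducible
  expect_identical(pp, init_policy(pc, seed = 51))
  expect_false(identical(pp$Wx, init_policy(pc, seed = 52)$Wx))
})

test_that("forward pass is deterministic without noise and bounded", {
  pp <- init_policy(pc, seed = 53)
  set.seed(54)
  obs <- matrix(rnorm(2 * 19), 2, 19)
  h <- matrix(rnorm(2 * pc$n_units, sd = 0.5), 2, pc$n_units)
  o1 <- policy_forward(pp, obs, h)
  o2 <- policy_forward(pp, obs, h)
  expect_identical(o1, o2)
  expect_true(all(abs(ad_value(o1$hidden)) < 1))
  expect_true(all(ad_value(o1$action) > 0 & ad_value(o1$action) < 1))
  # hidden noise perturbs the hidden state reproducibly
  set.seed(55); n1 <- policy_forward(pp, obs, h, sigma_h = 0.1)
  set.seed(55); n2 <- policy_forward(pp, obs, h, sigma_h = 0.1)
  expect_identical(n1, n2)
  expect_false(identical(ad_value(n1$hidden), ad_value(o1$hidden)))
})

test_that("policy gradients w.r.t. observations match finite differences", {
  pp <- init_policy(pc, seed = 56)
  set.seed(57)
  obs0 <- matrix(rnorm(19), 1, 19)
  h0 <- matrix(rnorm(pc$n_units, sd = 0.3), 1, pc$n_units)
  val <- function(o) {
    ad_begin(); on.exit(ad_end())
    ad_value(v_sum(policy_forward(pp, ad_var(o), h0)$action))[1]
  }
  ad_begin()
  o <- ad_var(obs0)
  out <- v_sum(policy_forward(pp, o, h0)$action)
  ad_backward(out)
  g <- ad_grad(o)
  ad_end()
  gfd <- fd_grad(val, obs0)
  expect_lt(max(abs(g - gfd)), 1e-6)
  expect_gt(max(abs(g)), 0)
  # fused and primitive GRU kernels agree exactly
  ad_begin()
  o1 <- ad_var(obs0)
  a1 <- policy_forward(pp, o1, h0, engine = "auto")
  ad_backward(v_sum(a1$action)); g1 <- ad_grad(o1)
  ad_end()
  ad_begin()
  o2 <- ad_var(obs0)
  a2 <- policy_forward(pp, o2, h0, engine = "primitive")
  ad_backward(v_sum(a2$action)); g2 <- ad_grad(o2)
  ad_end()
  expect_equal(ad_value(a1$action), ad_value(a2$action), tolerance = 1e-14)
  expect_lt(max(abs(g1 - g2)), 1e-13)
})

test_that("positional loss is zero inside the radius and L1 outside", {
  expect_equal(as.numeric(positional_loss(matrix(c(0.005, 0), 1),
                                          matrix(c(0, 0), 1), r = 0.01)), 0)
  expect_equal(as.numeric(positional_loss(matrix(c(0.03, 0.04), 1),
                                          matrix(c(0, 0), 1), r = 0.01)), 0.07)
  expect_equal(as.numeric(positional_loss(matrix(c(0.2, -0.1), 1),
                                          matrix(c(0.2, -0.1), 1))), 0)
  # radius uses the Euclidean norm: (0.008, 0.008) has L2 > 0.01
  expect_equal(as.numeric(positional_loss(matrix(c(0.008, 0.008), 1),
                                          matrix(c(0, 0), 1), r = 0.01)), 0.016)
})

test_that("muscle loss matches its printed form and scaling law", {
  f <- rep(500, 4)
  expect_equal(as.numeric(muscle_loss(matrix(0, 1, 4), f)), 0)
  expect_equal(as.numeric(muscle_loss(matrix(1, 1, 4), f)), 4e-6)
  u <- matrix(c(0.3, 0.1, 0.5, 0.2), 1)
  l1 <- as.numeric(muscle_loss(u, f))
  l2 <- as.numeric(muscle_loss(u, 2 * f))
  expect_equal(l2, l1 / 4)
  expect_error(muscle_loss(matrix(0, 1, 3), f), "mismatch")
  # alternative reading available behind the switch
  alt <- as.numeric(muscle_loss(u, f, form = "sum_squares"))
  expect_equal(alt, sum((u * f)^2) / sum(f^2))
})

test_that("hidden loss penalizes amplitude and change", {
  n <- 10
  expect_equal(as.numeric(hidden_loss(matrix(0, 1, n), matrix(0, 1, n))), 0)
  expect_equal(as.numeric(hidden_loss(matrix(1, 1, n), matrix(0, 1, n))), 1)
  quiet <- as.numeric(hidden_loss(matrix(0.5, 1, n), matrix(0, 1, n)))
  oscillating <- as.numeric(hidden_loss(matrix(0.5, 1, n), matrix(1, 1, n)))
  expect_gt(oscillating, quiet)
})

test_that("total loss composes the terms and isolates the kernel penalty", {
  Wx <- matrix(c(3, 4), 1) # Frobenius norm 5
  n <- 4
  rec0 <- list(x = list(matrix(c(0.1, 0.1), 1)),
               xstar = list(matrix(c(0.1, 0.1), 1)),
               u = list(matrix(0, 1, 2)),
               h = list(matrix(0, 1, n)), hdot = list(matrix(0, 1, n)))
  f <- c(500, 500)
  expect_equal(as.numeric(total_loss(rec0, f, Wx, loss_config(lambda = 0))), 0)
  expect_equal(as.numeric(total_loss(rec0, f, Wx, loss_config(lambda = 0.1))), 0.5)
  # alpha scales only the positional contribution
  rec1 <- rec0
  rec1$x <- list(matrix(c(0.3, 0.1), 1))
  l_a2 <- as.numeric(total_loss(rec1, f, Wx, loss_config(alpha = 2, lambda = 0)))
  l_a4 <- as.numeric(total_loss(rec1, f, Wx, loss_config(alpha = 4, lambda = 0)))
  expect_equal(l_a4, 2 * l_a2)
  expect_error(total_loss(list(x = list()), f, Wx), "empty")
})
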