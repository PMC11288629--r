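P <- two_link_params()
paths <- arm26_muscle_paths()
pm <- ReluPointMass24()

test_that("path points resolve through rigid-body frames", {
  sf <- paths$SF
  # world anchor is returned verbatim at any posture
  for (q in list(c(0, 0), c(1, 0.5), c(2, 2))) {
    pts <- resolve_path_points(sf, joint_state(q), P)
    expect_equal(as.numeric(pts[[1]]), c(-0.15, 0.03))
  }
  # bone point at zero rotation is its bone-frame coordinates
  pts0 <- resolve_path_points(sf, joint_state(c(0, 0)), P)
  expect_equal(as.numeric(pts0[[2]]), c(0.094, 0.017))
  # quarter turn of the shoulder
  pts90 <- resolve_path_points(sf, joint_state(c(deg(90), 0)), P)
  expect_equal(as.numeric(pts90[[2]]), c(-0.017, 0.094), tolerance = 1e-12)
  expect_error(resolve_path_points(muscle_path(c(0, 3), c(0, 0), c(0, 0)),
                                   joint_state(c(0, 0)), P), "body")
})

test_that("musculotendon length sums Euclidean segments", {
  expect_equal(as.numeric(musculotendon_length(list(matrix(c(0, 0), 1),
                                                    matrix(c(3, 4), 1)))), 5)
  expect_equal(as.numeric(musculotendon_length(list(matrix(c(0, 0), 1),
                                                    matrix(c(1, 0), 1),
                                                    matrix(c(1, 1), 1)))), 2)
  # collinear midpoint insertion leaves the length unchanged
  expect_equal(as.numeric(musculotendon_length(list(matrix(c(0, 0), 1),
                                                    matrix(c(1.5, 2), 1),
                                                    matrix(c(3, 4), 1)))), 5)
})

test_that("analytic moment arms equal finite differences of path length (256 states)", {
  set.seed(21)
  h <- 1e-4
  for (rep in 1:4) {
    B <- 32L
    q <- cbind(runif(B, 0.05, 2.3), runif(B, 0.05, 2.6))
    for (nm in names(paths)) {
      ma <- geometric_moment_arms(paths[[nm]], list(q = q), P)
      lenfun <- function(qq) as.numeric(
        musculotendon_length(resolve_path_points(paths[[nm]], list(q = qq), P)))
      for (j in 1:2) {
        e <- matrix(0, B, 2); e[, j] <- h
        fd <- (lenfun(q + e) - lenfun(q - e)) / (2 * h)
        got <- if (j == 1) ma$ma1 else ma$ma2
        expect_lt(max(abs(as.numeric(got) - fd)), 1e-6)
      }
    }
    # point-mass paths too
    qpm <- cbind(runif(B, -0.9, 0.9), runif(B, -0.9, 0.9))
    mapm <- geometric_moment_arms(pm$paths, list(q = qpm), pm$P)
    for (k in seq_along(pm$paths)) {
      lenfun <- function(qq) as.numeric(
        musculotendon_length(resolve_path_points(pm$paths[[k]], list(q = qq), pm$P)))
      for (j in 1:2) {
        e <- matrix(0, B, 2); e[, j] <- h
        fd <- (lenfun(qpm + e) - lenfun(qpm - e)) / (2 * h)
        got <- ad_value(if (j == 1) mapm$ma1 else mapm$ma2)[, k]
        expect_lt(max(abs(got - fd)), 1e-6)
      }
    }
  }
})

test_that("mono-articular elbow extensor has exactly zero shoulder moment arm", {
  set.seed(22)
  for (i in 1:10) {
    q <- c(runif(1, 0, 2.3), runif(1, 0.1, 2.6))
    ma <- geometric_moment_arms(paths$EE, joint_state(q), P)
    expect_lt(abs(ma[1, 1]), 1e-12)
    expect_gt(ma[1, 2], 0) # extensor: lengthens as the elbow flexes
  }
})

test_that("point-mass moment arms follow the 'X' geometry", {
  # upper-right muscle at the origin: shortening pulls toward (2, 2),
  # increasing both coordinates, so both moment arms are -sqrt(2)/2
  ma0 <- geometric_moment_arms(pm$paths$UR, joint_state(c(0, 0)), pm$P)
  expect_equal(as.numeric(ma0), c(-sqrt(2) / 2, -sqrt(2) / 2), tolerance = 1e-12)
  # identical at opposite positions on the aligned diagonal
  ma_a <- geometric_moment_arms(pm$paths$UR, joint_state(c(0.9, 0.9)), pm$P)
  ma_b <- geometric_moment_arms(pm$paths$UR, joint_state(c(-0.9, -0.9)), pm$P)
  expect_equal(ma_a, ma_b, tolerance = 1e-12)
  # and constant along that diagonal
  ma_c <- geometric_moment_arms(pm$paths$UR, joint_state(c(0.3, 0.3)), pm$P)
  expect_equal(ma_a, ma_c, tolerance = 1e-12)
  # lower-right muscle at the centre: negative w.r.t. x, positive w.r.t. y
  ma_lr <- geometric_moment_arms(pm$paths$LR, joint_state(c(0, 0)), pm$P)
  expect_lt(ma_lr[1, 1], 0)
  expect_gt(ma_lr[1, 2], 0)
})

test_that("polynomial lengths and moment arms are exact derivatives", {
  tbl <- arm26_polynomial_table()
  # mono-articular shoulder muscles have identically zero elbow moment arm
  set.seed(23)
  for (i in 1:5) {
    st <- joint_state(runif(2, 0, 2))
    g <- polynomial_length_and_moment_arms(tbl, st)
    expect_equal(g$ma2[1, tbl$muscle == "SF"], 0)
    expect_equal(g$ma2[1, tbl$muscle == "SE"], 0)
    # mono-articular elbow muscles: zero shoulder moment arm
    expect_equal(g$ma1[1, tbl$muscle == "EF"], 0)
    expect_equal(g$ma1[1, tbl$muscle == "EE"], 0)
  }
  # elbow-flexor elbow moment arm is affine in the elbow angle and
  # independent of the shoulder angle
  i_ef <- which(tbl$muscle == "EF")
  te <- c(0.3, 0.9, 1.5)
  mas <- vapply(te, function(t2)
    polynomial_length_and_moment_arms(tbl, joint_state(c(0.5, t2)))$ma2[1, i_ef],
    numeric(1))
  expect_equal(mas, tbl$a1e[i_ef] + 2 * tbl$a2e[i_ef] * te)
  ma_other_ts <- polynomial_length_and_moment_arms(tbl, joint_state(c(1.9, 0.9)))$ma2[1, i_ef]
  expect_equal(ma_other_ts, mas[2])
  # degenerate: only a0 -> constant length, zero moment arms
  cf0 <- data.frame(muscle = "x", a0 = 0.2, a1s = 0, a1e = 0, a2e = 0)
  g0 <- polynomial_length_and_moment_arms(cf0, joint_state(c(1, 1)))
  expect_equal(as.numeric(g0$len), 0.2)
  expect_equal(c(g0$ma1, g0$ma2), c(0, 0))
  # moment arms equal finite differences of the polynomial length
  h <- 1e-6
  q <- c(1.1, 0.7)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    fd <- (polynomial_length_and_moment_arms(tbl, joint_state(q + e))$len -
             polynomial_length_and_moment_arms(tbl, joint_state(q - e))$len) / (2 * h)
    got <- polynomial_length_and_moment_arms(tbl, joint_state(q))[[paste0("ma", j)]]
    expect_equal(as.numeric(got), as.numeric(fd), tolerance = 1e-7)
  }
})

test_that("bi-articular flexor moment arms are negative over the joint box", {
  tbl <- arm26_polynomial_table()
  i_bf <- which(tbl$muscle == "BF")
  grid <- expand.grid(q1 = seq(0, 135, by = 27) * pi / 180,
                      q2 = seq(0, 155, by = 31) * pi / 180)
  g <- polynomial_length_and_moment_arms(tbl, list(q = as.matrix(grid)))
  expect_true(all(g$ma1[, i_bf] < 0))
  expect_true(all(g$ma2[, i_bf] < 0))
})

test_that("muscle torques map through moment arms with the pulling sign", {
  expect_equal(muscle_torque(matrix(c(0.03, 0), 1), 0), c(0, 0))
  expect_equal(muscle_torque(matrix(c(0.05, 0), 1), 100), c(-5, 0))
  expect_error(muscle_torque(matrix(0, 2, 2), c(1, 2, 3)), "mismatch")
  # symmetric 'X' at the centre: equal forces cancel exactly
  ma <- geometric_moment_arms(pm$paths, joint_state(c(0, 0)), pm$P)
  MA <- rbind(cbind(as.numeric(ma$ma1), as.numeric(ma$ma2)))
  expect_equal(muscle_torque(MA, rep(100, 4)), c(0, 0), tolerance = 1e-12)
})
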