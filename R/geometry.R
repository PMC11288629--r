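#' @title Muscle-path geometry and moment arms
#'
#' @description
#' A muscle path is an ordered list of fixation points, each given in the
#' coordinate frame of the body it attaches to: body 0 is the world frame
#' (general coordinates), body `b >= 1` is a bone. On a bone, the first
#' coordinate runs along the bone from its origin and the second is the
#' orthogonal offset. The musculotendon length is the summed Euclidean
#' length of the straight segments joining consecutive points, and the
#' moment arm of a muscle with respect to a generalized coordinate `q_j`
#' is `d(length)/d(q_j)`: positive when the muscle lengthens as `q_j`
#' increases, so muscles whose shortening increases the coordinate have
#' negative moment arms.
#'
#' Moment arms are computed analytically (rigid-rotation derivatives of
#' the fixation points); the test-suite oracle re-derives them by central
#' finite differences of the path length. A polynomial approximation of
#' musculotendon length in the two joint angles is also provided for the
#' six-muscle arm, with moment arms as its exact partial derivatives.
#'
#' @name muscle_geometry
NULL

#' Construct a muscle path
#'
#' @param body integer vector of fixation bodies per point (0 = world)
#' @param x,y numeric vectors of first/second coordinates per point (m)
#' @param name muscle name
#' @return object of class `muscle_path`
#' @export
muscle_path <- function(body, x, y, name = "muscle") {
  stopifnot(length(body) >= 2, length(body) == length(x),
            length(body) == length(y), all(body >= 0))
  structure(list(body = as.integer(body), x = as.numeric(x),
                 y = as.numeric(y), name = name),
            class = "muscle_path")
}

# world positions of every fixation point of a path, plus their partial
# derivatives w.r.t. each generalized coordinate. Batch over B states.
# Returns list(points = list of Bx2, derivs = list over dof of list of Bx2).
.path_points_and_derivs <- function(path, q, params) {
  B <- nrow(ad_value(q))
  arm <- inherits(params, "two_link_params")
  if (arm) {
    q1 <- v_cols(q, 1L); q12 <- q1 + v_cols(q, 2L)
    c1 <- cos(q1); s1 <- sin(q1); c12 <- cos(q12); s12 <- sin(q12)
    ex <- params$L1 * c1; ey <- params$L1 * s1 # elbow position
  }
  zero2 <- matrix(0, B, 2L)
  pts <- vector("list", length(path$body))
  d1 <- vector("list", length(path$body))
  d2 <- vector("list", length(path$body))
  for (i in seq_along(path$body)) {
    b <- path$body[i]; cx <- path$x[i]; cy <- path$y[i]
    if (b == 0L) {
      pts[[i]] <- matrix(c(rep(cx, B), rep(cy, B)), B, 2L)
      d1[[i]] <- zero2; d2[[i]] <- zero2
    } else if (!arm) {
      # point-mass: the single movable body translates with q, no rotation
      px <- v_cols(q, 1L) + cx; py <- v_cols(q, 2L) + cy
      pts[[i]] <- v_cbind(px, py)
      d1[[i]] <- matrix(c(rep(1, B), rep(0, B)), B, 2L)
      d2[[i]] <- matrix(c(rep(0, B), rep(1, B)), B, 2L)
    } else if (b == 1L) {
      px <- cx * c1 - cy * s1; py <- cx * s1 + cy * c1
      pts[[i]] <- v_cbind(px, py)
      d1[[i]] <- v_cbind(-py, px) # rotation about the shoulder
      d2[[i]] <- zero2
    } else if (b == 2L) {
      rx <- cx * c12 - cy * s12; ry <- cx * s12 + cy * c12
      px <- ex + rx; py <- ey + ry
      pts[[i]] <- v_cbind(px, py)
      d1[[i]] <- v_cbind(-py, px)   # whole chain rotates with the shoulder
      d2[[i]] <- v_cbind(-ry, rx)   # distal frame rotates about the elbow
    } else {
      stop("unknown fixation body index: ", b, call. = FALSE)
    }
  }
  list(points = pts, d1 = d1, d2 = d2)
}

#' Resolve a muscle path to world coordinates
#'
#' Body-0 (world) points are returned verbatim; bone points are mapped by
#' the bone's rigid rotation and translation at the given joint state.
#'
#' @param path [muscle_path()]
#' @param state joint state (`B x dof`)
#' @param params skeleton parameters ([two_link_params()] or
#'   [point_mass_params()])
#' @return list of `B x 2` world-coordinate matrices, one per fixation point
#' @export
resolve_path_points <- function(path, state, params) {
  .path_points_and_derivs(path, state$q, params)$points
}

#' Musculotendon length of a resolved path
#'
#' @param points list of `B x 2` world points (from [resolve_path_points()])
#' @return `B x 1` summed Euclidean segment length (m)
#' @export
musculotendon_length <- function(points) {
  stopifnot(length(points) >= 2)
  len <- NULL
  for (i in seq_len(length(points) - 1L)) {
    d <- points[[i + 1L]] - points[[i]]
    seg <- sqrt(v_rowsums(d * d))
    len <- if (is.null(len)) seg else len + seg
  }
  len
}

# length, moment arms and (optionally) length rate for one path; batched.
# Returns list(len = Bx1, ma = list(Bx1 per dof)).
.path_geometry <- function(path, q, params) {
  pd <- .path_points_and_derivs(path, q, params)
  pts <- pd$points
  len <- NULL; ma1 <- NULL; ma2 <- NULL
  for (i in seq_len(length(pts) - 1L)) {
    d <- pts[[i + 1L]] - pts[[i]]
    seg <- sqrt(v_rowsums(d * d))
    sv <- ad_value(seg)
    if (any(sv < 1e-12))
      stop("degenerate path: zero-length segment in ", path$name, call. = FALSE)
    u <- v_mul(d, 1 / seg) # unit vector along the segment
    dd1 <- pd$d1[[i + 1L]] - pd$d1[[i]]
    dd2 <- pd$d2[[i + 1L]] - pd$d2[[i]]
    c1 <- v_rowsums(u * dd1)
    c2 <- v_rowsums(u * dd2)
    len <- if (is.null(len)) seg else len + seg
    ma1 <- if (is.null(ma1)) c1 else ma1 + c1
    ma2 <- if (is.null(ma2)) c2 else ma2 + c2
  }
  list(len = len, ma = list(ma1, ma2))
}

#' Geometric moment arms of muscle paths
#'
#' Analytic partial derivatives of musculotendon length with respect to
#' each generalized coordinate, evaluated at the current state.
#'
#' @param paths a single [muscle_path()] or a list of them
#' @param state joint state (`B x dof`)
#' @param params skeleton parameters
#' @return for a single path and B = 1, a `1 x dof` matrix; otherwise a
#'   list with `len` (`B x m`) and per-dof moment-arm matrices `ma1`,
#'   `ma2` (`B x m`)
#' @export
geometric_moment_arms <- function(paths, state, params) {
  single <- inherits(paths, "muscle_path")
  if (single) paths <- list(paths)
  gs <- lapply(paths, .path_geometry, q = state$q, params = params)
  len <- do.call(v_cbind, lapply(gs, `[[`, "len"))
  ma1 <- do.call(v_cbind, lapply(gs, function(g) g$ma[[1L]]))
  ma2 <- do.call(v_cbind, lapply(gs, function(g) g$ma[[2L]]))
  if (single && nrow(ad_value(len)) == 1L)
    return(matrix(c(ad_value(ma1), ad_value(ma2)), 1L, 2L,
                  dimnames = list(NULL, c("dof1", "dof2"))))
  list(len = len, ma1 = ma1, ma2 = ma2)
}

#' Polynomial moment-arm coefficients for the six-muscle arm
#'
#' Musculotendon length is approximated per muscle as a polynomial in the
#' shoulder angle `ts` and elbow angle `te` (radians):
#' `len = a0 + a1s*ts + a1e*te + a2e*te^2`; moment arms are its exact
#' partial derivatives. Mono-articular muscles have zero coefficients at
#' the unspanned joint and hence exactly zero moment arm there. The
#' bi-articular-flexor shoulder coefficient is -0.03 m/rad (see the
#' methods vignette on coefficient provenance).
#'
#' @return data.frame with columns `muscle`, `a0`, `a1s`, `a1e`, `a2e`
#' @export
arm26_polynomial_table <- function() {
  data.frame(
    muscle = c("SF", "SE", "EF", "EE", "BF", "BE"),
    a0  = c(0.151, 0.2322, 0.2859, 0.2355, 0.3329, 0.2989),
    a1s = c(-0.03, 0.03, 0, 0, -0.03, 0.03),
    a1e = c(0, 0, -0.014, 0.025, -0.016, 0.03),
    a2e = c(0, 0, -4.0e-3, -2.2e-3, -5.7e-3, -3.2e-3),
    stringsAsFactors = FALSE
  )
}

#' Polynomial musculotendon length and moment arms
#'
#' @param coeffs data.frame as [arm26_polynomial_table()] (columns `a0`,
#'   `a1s`, `a1e`, `a2e`; m muscles)
#' @param state joint state with `q` = `B x 2` (shoulder, elbow) in radians
#' @return list with `len` (`B x m`), `ma1` (shoulder moment arms,
#'   `B x m`), `ma2` (elbow moment arms, `B x m`)
#' @export
polynomial_length_and_moment_arms <- function(coeffs, state) {
  stopifnot(all(coeffs$a0 > 0))
  ts <- v_cols(state$q, 1L); te <- v_cols(state$q, 2L)
  a0 <- matrix(coeffs$a0, 1L); a1s <- matrix(coeffs$a1s, 1L)
  a1e <- matrix(coeffs$a1e, 1L); a2e <- matrix(coeffs$a2e, 1L)
  len <- v_add(a0, v_mm(ts, a1s) + v_mm(te, a1e) + v_mm(te * te, a2e))
  B <- nrow(ad_value(ts))
  ma1 <- a1s[rep.int(1L, B), , drop = FALSE] # constant in q
  ma2 <- v_add(a1e, 2 * v_mm(te, a2e))
  list(len = len, ma1 = ma1, ma2 = ma2)
}

#' Map muscle forces to generalized forces through moment arms
#'
#' A pulling (tensile, nonnegative) muscle force drives each coordinate in
#' the direction that shortens the muscle: `tau_j = -sum_m MA[m, j] * F[m]`.
#'
#' @param moment_arms `m x dof` moment-arm matrix (m or m/rad)
#' @param forces length-m nonnegative muscle forces (N)
#' @return length-dof generalized force vector (N m or N)
#' @export
muscle_torque <- function(moment_arms, forces) {
  moment_arms <- as.matrix(moment_arms)
  if (nrow(moment_arms) != length(forces))
    stop("shape mismatch: ", nrow(moment_arms), " muscles vs ",
         length(forces), " forces", call. = FALSE)
  as.numeric(-crossprod(moment_arms, forces))
}

# batched torque: ma_list = list of Bxm per dof, forces Bxm -> Bxdof
.muscle_torque_batch <- function(ma_list, forces) {
  taus <- lapply(ma_list, function(ma) -v_rowsums(ma * forces))
  do.call(v_cbind, taus)
}

#' Muscle paths for the six-muscle planar arm
#'
#' Fixation points per muscle: body index (0 = world, 1 = upper arm,
#' 2 = forearm) and bone-relative coordinates (m). The shoulder is at the
#' world origin.
#'
#' @return named list of [muscle_path()] objects (SF, SE, EF, EE, BF, BE)
#' @export
arm26_muscle_paths <- function() {
  list(
    SF = muscle_path(c(0, 1), c(-0.15, 0.094), c(0.03, 0.017), "SF"),
    SE = muscle_path(c(0, 0, 1), c(-0.013, 0.05, 0.153), c(-0.07, 0, 0), "SE"),
    EF = muscle_path(c(1, 2), c(0.23, 0.231), c(0.001, 0.01), "EF"),
    EE = muscle_path(c(1, 1, 2), c(0.03, 0.138, -0.04), c(0, -0.019, -0.017), "EE"),
    BF = muscle_path(c(0, 2), c(-0.052, 0.044), c(0.033, 0.001), "BF"),
    BE = muscle_path(c(0, 2), c(0.02, -0.04), c(-0.028, -0.017), "BE")
  )
}

#' Muscle paths for the four-muscle point-mass ('X' configuration)
#'
#' Four muscles anchor at the workspace corners (2, 2), (2, -2), (-2, -2),
#' (-2, 2) (upper right, lower right, lower left, upper left) and insert
#' on the point-mass itself.
#'
#' @return named list of [muscle_path()] objects
#' @export
pointmass_muscle_paths <- function() {
  anchors <- list(UR = c(2, 2), LR = c(2, -2), LL = c(-2, -2), UL = c(-2, 2))
  lapply(names(anchors), function(nm) {
    a <- anchors[[nm]]
    muscle_path(c(0, 1), c(a[1], 0), c(a[2], 0), nm)
  }) |> stats::setNames(names(anchors))
}
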