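#' @title Reverse-mode automatic differentiation tape
#'
#' @description
#' A minimal reverse-mode autodiff engine operating on numeric matrices.
#' Every differentiable quantity in a recording is an `advar` node holding a
#' `batch x k` value matrix. Operations on nodes append to a global tape;
#' [ad_backward()] replays the tape in reverse, accumulating vector-Jacobian
#' products. This is the primitive that makes the effector physics
#' differentiable end-to-end, so that a recurrent policy can be trained by
#' gradient descent *through* the biomechanics.
#'
#' Supported broadcasting for elementwise ops: equal shapes, `1 x 1` scalars,
#' `1 x k` row vectors against `B x k`, and `B x 1` columns against `B x k`.
#' Gradients are summed over broadcast dimensions.
#'
#' Plain matrices mix freely with nodes: an operation with at least one
#' `advar` operand records to the tape, treating plain-matrix operands as
#' constants. The `v_*` helpers (e.g. [v_mm()], [v_clamp()]) dispatch on
#' whether any argument is an `advar`, so model code written once runs both
#' as a fast plain-numeric simulation and as a recorded differentiable graph.
#'
#' @name autograd
NULL

.ad <- new.env(parent = emptyenv())
.ad$active <- FALSE
.ad$counter <- 0L

#' Start a recording (resets the node counter)
#'
#' The graph itself lives in the nodes (each records its parents and a
#' vector-Jacobian product closure); [ad_backward()] recovers evaluation
#' order from the monotone node ids, so no global node list is kept.
#' @return invisibly, NULL
#' @export
ad_begin <- function() {
  .ad$active <- TRUE
  .ad$counter <- 0L
  invisible(NULL)
}

#' Stop recording
#' @return invisibly, NULL
#' @export
ad_end <- function() {
  .ad$active <- FALSE
  invisible(NULL)
}

#' Is a recording active?
#' @return logical flag
#' @export
ad_active <- function() .ad$active

.ad_node <- function(value, parents = NULL, vjp = NULL) {
  if (!.ad$active) stop("no active recording; call ad_begin() first", call. = FALSE)
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$g <- NULL
  e$parents <- parents
  e$vjp <- vjp
  e$id <- .ad$counter <- .ad$counter + 1L
  class(e) <- "advar"
  e
}

#' Create a leaf (parameter/input) node on the active tape
#' @param value numeric matrix (vectors are promoted to 1-row matrices)
#' @return an `advar` node
#' @export
ad_var <- function(value) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  .ad_node(value)
}

#' Test for an autodiff node
#' @param x object
#' @return logical
#' @export
is.advar <- function(x) inherits(x, "advar")

#' Numeric value of a node (or pass through a plain matrix)
#' @param x `advar` or matrix
#' @return numeric matrix
#' @export
ad_value <- function(x) if (is.advar(x)) x$v else x

#' Accumulated gradient of a node after [ad_backward()]
#' @param x `advar`
#' @return gradient matrix (NULL if no gradient reached the node)
#' @export
ad_grad <- function(x) x$g

#' @export
print.advar <- function(x, ...) {
  cat("<advar ", nrow(x$v), "x", ncol(x$v), " id=", x$id, ">\n", sep = "")
  invisible(x)
}

#' @export
dim.advar <- function(x) dim(x$v)

# --- broadcasting helpers ----------------------------------------------------

# expand value `v` to shape (B, k); return expanded matrix
.bc_expand <- function(v, B, k) {
  dv <- dim(v)
  if (dv[1L] == B && dv[2L] == k) return(v)
  if (dv[1L] == 1L && dv[2L] == 1L) return(matrix(v[1L], B, k))
  if (dv[1L] == 1L && dv[2L] == k) return(v[rep.int(1L, B), , drop = FALSE])
  if (dv[1L] == B && dv[2L] == 1L) return(v[, rep.int(1L, k), drop = FALSE])
  stop("non-broadcastable shapes: ", dv[1L], "x", dv[2L], " vs ", B, "x", k,
       call. = FALSE)
}

# reduce gradient `g` (B x k) back to original shape `dv`
.bc_reduce <- function(g, dv) {
  dg <- dim(g)
  if (dg[1L] == dv[1L] && dg[2L] == dv[2L]) return(g)
  if (dv[1L] == 1L && dv[2L] == 1L) return(matrix(sum(g), 1L, 1L))
  if (dv[1L] == 1L) return(matrix(colSums(g), 1L, dv[2L]))
  if (dv[2L] == 1L) return(matrix(rowSums(g), dv[1L], 1L))
  stop("cannot reduce gradient", call. = FALSE)
}

.as_val <- function(x) {
  if (is.advar(x)) return(x$v)
  if (is.matrix(x)) return(x)
  matrix(x, nrow = 1L)
}

# --- arithmetic --------------------------------------------------------------

#' @export
Ops.advar <- function(e1, e2) {
  op <- .Generic
  if (missing(e2)) { # unary
    if (op == "-") {
      return(.ad_node(-e1$v, list(e1), function(g) list(-g)))
    }
    if (op == "+") return(e1)
    stop("unsupported unary op for advar: ", op, call. = FALSE)
  }
  if (op %in% c("==", "!=", "<", ">", "<=", ">=")) {
    return(get(op)(.as_val(e1), .as_val(e2)))
  }
  v1 <- .as_val(e1); v2 <- .as_val(e2)
  d1 <- dim(v1); d2 <- dim(v2)
  B <- max(d1[1L], d2[1L]); k <- max(d1[2L], d2[2L])
  a <- .bc_expand(v1, B, k); b <- .bc_expand(v2, B, k)
  p1 <- if (is.advar(e1)) e1 else NULL
  p2 <- if (is.advar(e2)) e2 else NULL
  mk <- function(val, g1fun, g2fun) {
    parents <- c(if (!is.null(p1)) list(p1), if (!is.null(p2)) list(p2))
    vjp <- function(g) {
      out <- list()
      if (!is.null(p1)) out <- c(out, list(.bc_reduce(g1fun(g), d1)))
      if (!is.null(p2)) out <- c(out, list(.bc_reduce(g2fun(g), d2)))
      out
    }
    .ad_node(val, parents, vjp)
  }
  switch(op,
    "+" = mk(a + b, function(g) g, function(g) g),
    "-" = mk(a - b, function(g) g, function(g) -g),
    "*" = mk(a * b, function(g) g * b, function(g) g * a),
    "/" = mk(a / b, function(g) g / b, function(g) -g * a / (b * b)),
    "^" = {
      if (is.advar(e2)) stop("advar exponent not supported", call. = FALSE)
      val <- a^b
      mk(val, function(g) g * b * a^(b - 1), function(g) NULL)
    },
    stop("unsupported op for advar: ", op, call. = FALSE)
  )
}

#' @export
Math.advar <- function(x, ...) {
  v <- x$v
  switch(.Generic,
    exp  = { val <- exp(v);  .ad_node(val, list(x), function(g) list(g * val)) },
    log  = .ad_node(log(v),  list(x), function(g) list(g / v)),
    sqrt = { val <- sqrt(v); .ad_node(val, list(x), function(g) list(g * 0.5 / val)) },
    tanh = { val <- tanh(v); .ad_node(val, list(x), function(g) list(g * (1 - val * val))) },
    sin  = .ad_node(sin(v),  list(x), function(g) list(g * cos(v))),
    cos  = .ad_node(cos(v),  list(x), function(g) list(-g * sin(v))),
    abs  = .ad_node(abs(v),  list(x), function(g) list(g * sign(v))),
    stop("unsupported Math op for advar: ", .Generic, call. = FALSE)
  )
}

# --- structural & composite ops ---------------------------------------------

#' Matrix product (autodiff-aware)
#' @param x left operand, `B x I` (`advar` or matrix)
#' @param w right operand, `I x K` (`advar` or matrix)
#' @return product, recorded on the tape if any operand is an `advar`
#' @export
v_mm <- function(x, w) {
  if (!is.advar(x) && !is.advar(w)) return(x %*% w)
  vx <- .as_val(x); vw <- .as_val(w)
  parents <- c(if (is.advar(x)) list(x), if (is.advar(w)) list(w))
  vjp <- function(g) {
    out <- list()
    if (is.advar(x)) out <- c(out, list(g %*% t(vw)))
    if (is.advar(w)) out <- c(out, list(crossprod(vx, g)))
    out
  }
  .ad_node(vx %*% vw, parents, vjp)
}

#' Row sums kept as a column (autodiff-aware)
#' @param x `B x k` operand
#' @return `B x 1` row sums
#' @export
v_rowsums <- function(x) {
  if (!is.advar(x)) return(matrix(rowSums(x), nrow(x), 1L))
  k <- ncol(x$v)
  .ad_node(matrix(rowSums(x$v), nrow(x$v), 1L), list(x),
           function(g) list(g[, rep.int(1L, k), drop = FALSE]))
}

#' Sum of all elements as a 1x1 matrix (autodiff-aware)
#' @param x operand
#' @return `1 x 1` sum
#' @export
v_sum <- function(x) {
  if (!is.advar(x)) return(matrix(sum(x), 1L, 1L))
  dv <- dim(x$v)
  .ad_node(matrix(sum(x$v), 1L, 1L), list(x),
           function(g) list(matrix(g[1L], dv[1L], dv[2L])))
}

#' Mean of all elements as a 1x1 matrix (autodiff-aware)
#' @param x operand
#' @return `1 x 1` mean
#' @export
v_mean <- function(x) {
  n <- prod(dim(ad_value(x)))
  v_sum(x) / n
}

#' Column binding (autodiff-aware)
#' @param ... operands with equal row counts
#' @return column-concatenated result
#' @export
v_cbind <- function(...) {
  args <- list(...)
  if (!any(vapply(args, is.advar, logical(1L)))) return(do.call(cbind, args))
  vals <- lapply(args, .as_val)
  ks <- vapply(vals, ncol, integer(1L))
  ends <- cumsum(ks); starts <- ends - ks + 1L
  isv <- vapply(args, is.advar, logical(1L))
  parents <- args[isv]
  vjp <- function(g) {
    out <- vector("list", sum(isv)); j <- 0L
    for (i in seq_along(args)) {
      if (!isv[i]) next
      j <- j + 1L
      out[[j]] <- g[, starts[i]:ends[i], drop = FALSE]
    }
    out
  }
  .ad_node(do.call(cbind, vals), parents, vjp)
}

#' Column selection (autodiff-aware)
#' @param x operand
#' @param j column indices
#' @return selected columns
#' @export
v_cols <- function(x, j) {
  if (!is.advar(x)) return(x[, j, drop = FALSE])
  dv <- dim(x$v)
  .ad_node(x$v[, j, drop = FALSE], list(x), function(g) {
    gz <- matrix(0, dv[1L], dv[2L])
    gz[, j] <- gz[, j, drop = FALSE] + g
    list(gz)
  })
}

#' Row binding of a list of operands (autodiff-aware)
#' @param lst list of operands with equal column counts
#' @return row-concatenated result
#' @export
v_rbind <- function(lst) {
  isv <- vapply(lst, is.advar, logical(1L))
  if (!any(isv)) return(do.call(rbind, lst))
  vals <- lapply(lst, .as_val)
  Bs <- vapply(vals, nrow, integer(1L))
  ends <- cumsum(Bs); starts <- ends - Bs + 1L
  parents <- lst[isv]
  vjp <- function(g) {
    out <- vector("list", sum(isv)); j <- 0L
    for (i in seq_along(lst)) {
      if (!isv[i]) next
      j <- j + 1L
      out[[j]] <- g[starts[i]:ends[i], , drop = FALSE]
    }
    out
  }
  .ad_node(do.call(rbind, vals), parents, vjp)
}

#' Clamp to a constant interval (autodiff-aware; subgradient 0 where clamped)
#' @param x operand
#' @param lo,hi scalar bounds (may be -Inf/Inf)
#' @return clamped values
#' @export
v_clamp <- function(x, lo = -Inf, hi = Inf) {
  if (!is.advar(x)) return(pmin(pmax(x, lo), hi))
  v <- x$v
  val <- pmin(pmax(v, lo), hi)
  mask <- (v > lo & v < hi) * 1
  .ad_node(val, list(x), function(g) list(g * mask))
}

#' Elementwise selection by a constant mask (autodiff-aware)
#'
#' `mask` is a plain numeric/logical matrix (it is *not* differentiated
#' through); where it is 1/TRUE take `a`, else `b`. This is how piecewise
#' curves (force-velocity branches, activation/deactivation switching) are
#' expressed with subgradients.
#' @param mask plain 0/1 or logical matrix
#' @param a,b operands (advar or matrix), broadcastable to `mask`'s shape
#' @return selected values
#' @export
v_where <- function(mask, a, b) {
  m <- mask * 1
  m * a + (1 - m) * b
}

#' Logistic sigmoid (autodiff-aware)
#' @param x operand
#' @return `1/(1+exp(-x))`
#' @export
v_sigmoid <- function(x) {
  if (!is.advar(x)) return(1 / (1 + exp(-x)))
  s <- 1 / (1 + exp(-x$v))
  .ad_node(s, list(x), function(g) list(g * s * (1 - s)))
}

#' Broadcasting addition/multiplication for mixed shapes
#'
#' `advar` operands already broadcast through the `Ops` group method; these
#' helpers give plain matrices the same row-/column-vector broadcasting so
#' one code path serves both modes.
#' @param a,b operands (matrix or `advar`); shapes must be broadcastable
#'   (equal, `1 x 1`, `1 x k` vs `B x k`, or `B x 1` vs `B x k`)
#' @return elementwise result with the broadcast shape
#' @export
v_add <- function(a, b) {
  if (is.advar(a) || is.advar(b)) return(a + b)
  da <- dim(a); db <- dim(b)
  B <- max(da[1L], db[1L]); k <- max(da[2L], db[2L])
  .bc_expand(a, B, k) + .bc_expand(b, B, k)
}

#' @rdname v_add
#' @export
v_mul <- function(a, b) {
  if (is.advar(a) || is.advar(b)) return(a * b)
  da <- dim(a); db <- dim(b)
  B <- max(da[1L], db[1L]); k <- max(da[2L], db[2L])
  .bc_expand(a, B, k) * .bc_expand(b, B, k)
}

#' Stop-gradient: constant copy of a value
#' @param x operand
#' @return plain matrix (detached from the tape)
#' @export
v_detach <- function(x) ad_value(x)

#' Run backpropagation from a (scalar) root node
#'
#' Accumulates gradients into every node reachable from `root`; read them
#' with [ad_grad()]. The root's gradient is seeded with 1.
#' @param root `advar`, typically `1 x 1` (a loss)
#' @return invisibly, NULL
#' @export
ad_backward <- function(root) {
  stopifnot(is.advar(root))
  root$g <- matrix(1, nrow(root$v), ncol(root$v))
  # collect every node reachable from the root (iterative DFS); ids are
  # assigned in creation order, so descending-id traversal is a valid
  # reverse topological order
  maxid <- root$id
  nodes <- vector("list", maxid)
  seen <- logical(maxid)
  stack <- vector("list", 256L); stack[[1L]] <- root; sp <- 1L
  while (sp > 0L) {
    e <- stack[[sp]]; sp <- sp - 1L
    if (seen[e$id]) next
    seen[e$id] <- TRUE
    nodes[[e$id]] <- e
    for (p in e$parents) {
      if (!seen[p$id]) {
        sp <- sp + 1L
        if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
        stack[[sp]] <- p
      }
    }
  }
  for (i in seq.int(maxid, 1L)) {
    nd <- nodes[[i]]
    if (is.null(nd) || is.null(nd$g) || is.null(nd$vjp)) next
    gs <- nd$vjp(nd$g)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      p$g <- if (is.null(p$g)) gj else p$g + gj
    }
  }
  invisible(NULL)
}
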