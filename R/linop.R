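#' Linear operator with counted applications
#'
#' A lightweight container for a linear map, its adjoint and an upper bound on
#' its operator norm. Every application through [op_apply()] /
#' [op_apply_adjoint()] increments an internal counter, which is how the
#' package accounts for computational cost in forward-operator evaluations
#' (the hardware-independent cost unit used to compare the uncertainty
#' quantification stage against the reconstruction stage).
#'
#' Operators may act on plain matrices/arrays or on named lists of them
#' (product spaces); the solver treats both transparently.
#'
#' @param forward function mapping a domain element to a codomain element.
#' @param adjoint function implementing the adjoint map.
#' @param norm_bound scalar upper bound on the operator norm (used to set
#'   primal-dual step sizes; must dominate the power-iteration estimate).
#' @param name short label used in diagnostics.
#' @return An object of class `linear_op`.
#' @export
linear_op <- function(forward, adjoint, norm_bound, name = "op") {
  stopifnot(is.function(forward), is.function(adjoint),
            is.numeric(norm_bound), norm_bound >= 0)
  counts <- new.env(parent = emptyenv())
  counts$forward <- 0L
  counts$adjoint <- 0L
  structure(list(forward = forward, adjoint = adjoint,
                 norm_bound = norm_bound, name = name, counts = counts),
            class = "linear_op")
}

#' Apply a linear operator (counted)
#' @param op a [linear_op()].
#' @param x domain element.
#' @return codomain element.
#' @export
op_apply <- function(op, x) {
  op$counts$forward <- op$counts$forward + 1L
  op$forward(x)
}

#' Apply the adjoint of a linear operator (counted)
#' @param op a [linear_op()].
#' @param u codomain element.
#' @return domain element.
#' @export
op_apply_adjoint <- function(op, u) {
  op$counts$adjoint <- op$counts$adjoint + 1L
  op$adjoint(u)
}

#' Read the application counters of an operator
#' @param op a [linear_op()].
#' @return named integer vector with elements `forward` and `adjoint`.
#' @export
op_counts <- function(op) {
  c(forward = op$counts$forward, adjoint = op$counts$adjoint)
}

#' Reset the application counters of an operator
#' @param op a [linear_op()].
#' @return the operator, invisibly.
#' @export
op_reset_counts <- function(op) {
  op$counts$forward <- 0L
  op$counts$adjoint <- 0L
  invisible(op)
}

#' Relative adjoint-test discrepancy
#'
#' Computes |<Ax, u> - <x, A'u>| / max(|<Ax, u>|, |<x, A'u>|, eps) for given
#' probes. For a correctly matched operator pair this is at machine-precision
#' level. Does not touch the counters.
#'
#' @param op a [linear_op()].
#' @param x domain probe.
#' @param u codomain probe.
#' @return nonnegative scalar.
#' @export
adjoint_discrepancy <- function(op, x, u) {
  a <- vs_dot(op$forward(x), u)
  b <- vs_dot(x, op$adjoint(u))
  abs(a - b) / max(abs(a), abs(b), .Machine$double.eps)
}

#' Operator-norm estimate by power iteration
#'
#' Power iteration on A'A starting from a seeded random domain element.
#' Uncounted (norm estimation is setup, not solve-time cost).
#'
#' @param op a [linear_op()].
#' @param x0 starting domain element (nonzero).
#' @param iters number of iterations.
#' @param tol relative-change stopping tolerance on the estimate.
#' @return scalar estimate of the operator norm.
#' @export
estimate_op_norm <- function(op, x0, iters = 100, tol = 1e-7) {
  x <- vs_scale(x0, 1 / max(vs_norm(x0), .Machine$double.eps))
  est <- 0
  for (k in seq_len(iters)) {
    y <- op$adjoint(op$forward(x))
    new_est <- sqrt(max(vs_norm(y), 0))
    if (new_est == 0) return(0)
    x <- vs_scale(y, 1 / vs_norm(y))
    if (k > 1 && abs(new_est - est) <= tol * new_est) {
      est <- new_est
      break
    }
    est <- new_est
  }
  est
}

## Rescale an operator to unit norm bound, routing applications through the
## counted interface so the wrapped operator keeps accounting for cost.
## Dualized constraints are fed normalized operators (with centers/radii
## divided by the same factor — the same sets), which keeps the primal step
## size of the splitting solver from being crushed by stiff operators.
.unit_op <- function(op) {
  c0 <- op$norm_bound
  stopifnot(is.finite(c0), c0 > 0)
  list(op = linear_op(function(x) op_apply(op, x) / c0,
                      function(u) op_apply_adjoint(op, u) / c0,
                      norm_bound = 1, name = op$name),
       scale = c0)
}

## ---- product-space (vector space) helpers -------------------------------
## Iterates are matrices/arrays or named lists of them; these helpers give
## the few vector-space operations the solver needs, recursing over lists.

vs_map <- function(x, f) {
  if (!is.list(x)) return(f(x))
  out <- x
  for (i in seq_along(x)) out[[i]] <- vs_map(x[[i]], f)
  out
}

vs_map2 <- function(x, y, f) {
  if (!is.list(x)) return(f(x, y))
  out <- x
  for (i in seq_along(x)) out[[i]] <- vs_map2(x[[i]], y[[i]], f)
  out
}

vs_add <- function(x, y) vs_map2(x, y, `+`)
vs_sub <- function(x, y) vs_map2(x, y, `-`)
vs_scale <- function(x, s) vs_map(x, function(a) a * s)

vs_dot <- function(x, y) {
  if (!is.list(x)) return(sum(x * y))
  tot <- 0
  for (i in seq_along(x)) tot <- tot + vs_dot(x[[i]], y[[i]])
  tot
}

vs_norm <- function(x) sqrt(vs_dot(x, x))

vs_zero_like <- function(x) vs_map(x, function(a) a * 0)
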