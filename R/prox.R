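#' Projection onto the nonnegative orthant
#'
#' Componentwise `max(x, 0)`; the Euclidean projection onto the intensity
#' set `{x : x >= 0}`.
#'
#' @param x numeric vector/matrix/array.
#' @return same shape, componentwise clipped at zero.
#' @export
project_nonneg <- function(x) pmax(x, 0)

#' Projection onto an l2 ball
#'
#' Euclidean projection of `x` onto `{z : ||z - center||_2 <= radius}`:
#' identity inside the ball, radial shrinkage outside. Radius 0 returns the
#' center.
#'
#' @param x point to project (vector/matrix/array).
#' @param center ball center, same shape as `x` (or scalar, recycled).
#' @param radius nonnegative scalar.
#' @return projected point, same shape as `x`.
#' @export
project_l2_ball <- function(x, center, radius) {
  stopifnot(radius >= 0)
  d <- x - center
  nd <- sqrt(sum(d * d))
  if (nd <= radius) return(x)
  if (nd == 0) return(x)  # radius 0 and x at center
  center + d * (radius / nd)
}

#' Projection onto an l1 ball
#'
#' Euclidean projection onto `{z : ||z||_1 <= radius}` by the
#' sort-and-threshold (breakpoint) algorithm; exact for finite inputs and
#' idempotent. Ties between equal-magnitude entries are resolved by the
#' common soft threshold, which is deterministic.
#'
#' @param x numeric vector/matrix/array.
#' @param radius nonnegative scalar l1 budget.
#' @return projected point, same shape as `x`.
#' @export
project_l1_ball <- function(x, radius) {
  stopifnot(radius >= 0)
  a <- abs(x)
  if (sum(a) <= radius) return(x)
  if (radius == 0) return(x * 0)
  u <- sort(as.numeric(a), decreasing = TRUE)
  cs <- cumsum(u)
  k <- max(which(u - (cs - radius) / seq_along(u) > 0))
  theta <- (cs[k] - radius) / k
  sign(x) * pmax(a - theta, 0)
}

#' Soft-thresholding (proximity operator of the l1 norm)
#' @param x numeric vector/matrix/array.
#' @param tau threshold (>= 0).
#' @return `sign(x) * max(|x| - tau, 0)`.
#' @export
soft_threshold <- function(x, tau) sign(x) * pmax(abs(x) - tau, 0)

#' Forward finite-difference gradient of an image
#'
#' Forward differences along columns (horizontal channel 1) and rows
#' (vertical channel 2) with replicate (Neumann) boundary, so the last
#' difference along each axis is zero. Linear; its exact adjoint is
#' [div2d_adjoint()].
#'
#' @param x image matrix, at least 2 x 2.
#' @return array of dim `c(nrow, ncol, 2)`.
#' @export
grad2d <- function(x) {
  x <- as.matrix(x)
  nr <- nrow(x); nc <- ncol(x)
  stopifnot(nr >= 2, nc >= 2)
  g <- array(0, dim = c(nr, nc, 2))
  g[, -nc, 1] <- x[, -1] - x[, -nc]
  g[-nr, , 2] <- x[-1, ] - x[-nr, ]
  g
}

#' Adjoint of the finite-difference gradient (negative divergence)
#'
#' Exact adjoint of [grad2d()], satisfying `<grad2d(x), g> == <x,
#' div2d_adjoint(g)>` for all inputs.
#'
#' @param g gradient field, array of dim `c(nr, nc, 2)`.
#' @return image matrix `nr x nc`.
#' @export
div2d_adjoint <- function(g) {
  nr <- dim(g)[1]; nc <- dim(g)[2]
  out <- matrix(0, nr, nc)
  gh <- g[, , 1]
  # adjoint of column forward differences (last column of gh is inert)
  out[, 1] <- out[, 1] - gh[, 1]
  if (nc > 2) out[, 2:(nc - 1)] <- out[, 2:(nc - 1)] + gh[, 1:(nc - 2)] - gh[, 2:(nc - 1)]
  out[, nc] <- out[, nc] + gh[, nc - 1]
  gv <- g[, , 2]
  out[1, ] <- out[1, ] - gv[1, ]
  if (nr > 2) out[2:(nr - 1), ] <- out[2:(nr - 1), ] + gv[1:(nr - 2), ] - gv[2:(nr - 1), ]
  out[nr, ] <- out[nr, ] + gv[nr - 1, ]
  out
}

#' Gradient operator as a counted linear operator
#' @param image_side side of the square image domain.
#' @return a [linear_op()] with norm bound `sqrt(8)`.
#' @export
grad_op <- function(image_side) {
  linear_op(grad2d, div2d_adjoint, norm_bound = sqrt(8), name = "grad")
}

#' Per-pixel gradient magnitude
#' @param g output of [grad2d()].
#' @return matrix of Euclidean norms of the two channels.
#' @export
grad_magnitude <- function(g) sqrt(g[, , 1]^2 + g[, , 2]^2)

## ---- orthonormal 2-D Haar transform -------------------------------------

#' Orthonormal multilevel 2-D Haar analysis
#'
#' Separable Haar wavelet decomposition with the standard Mallat layout
#' (approximation block in the top-left corner). The transform is orthonormal,
#' so [haar_synthesis()] is both its inverse and its adjoint and the operator
#' norm is exactly 1.
#'
#' @param x square image matrix whose side is divisible by `2^levels`.
#' @param levels number of decomposition levels (>= 1).
#' @return coefficient matrix of the same size.
#' @export
haar_analysis <- function(x, levels = 3) {
  x <- as.matrix(x)
  s <- nrow(x)
  stopifnot(ncol(x) == s, levels >= 1, s %% (2^levels) == 0)
  out <- x
  m <- s
  for (l in seq_len(levels)) {
    b <- out[1:m, 1:m, drop = FALSE]
    odd <- seq(1, m, by = 2); even <- odd + 1
    # rows
    lo <- (b[odd, , drop = FALSE] + b[even, , drop = FALSE]) / sqrt(2)
    hi <- (b[odd, , drop = FALSE] - b[even, , drop = FALSE]) / sqrt(2)
    b <- rbind(lo, hi)
    # columns
    lo <- (b[, odd, drop = FALSE] + b[, even, drop = FALSE]) / sqrt(2)
    hi <- (b[, odd, drop = FALSE] - b[, even, drop = FALSE]) / sqrt(2)
    out[1:m, 1:m] <- cbind(lo, hi)
    m <- m / 2
  }
  out
}

#' Orthonormal multilevel 2-D Haar synthesis (inverse/adjoint of analysis)
#' @param w coefficient matrix from [haar_analysis()].
#' @param levels number of levels used in the analysis.
#' @return reconstructed image matrix.
#' @export
haar_synthesis <- function(w, levels = 3) {
  w <- as.matrix(w)
  s <- nrow(w)
  stopifnot(ncol(w) == s, levels >= 1, s %% (2^levels) == 0)
  out <- w
  for (l in rev(seq_len(levels))) {
    m <- s / (2^(l - 1))
    h <- m / 2
    b <- out[1:m, 1:m, drop = FALSE]
    # columns
    lo <- b[, 1:h, drop = FALSE]; hi <- b[, (h + 1):m, drop = FALSE]
    rec <- matrix(0, m, m)
    odd <- seq(1, m, by = 2); even <- odd + 1
    rec[, odd] <- (lo + hi) / sqrt(2)
    rec[, even] <- (lo - hi) / sqrt(2)
    # rows
    lo <- rec[1:h, , drop = FALSE]; hi <- rec[(h + 1):m, , drop = FALSE]
    rec2 <- matrix(0, m, m)
    rec2[odd, ] <- (lo + hi) / sqrt(2)
    rec2[even, ] <- (lo - hi) / sqrt(2)
    out[1:m, 1:m] <- rec2
    m <- m / 2
  }
  out
}
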