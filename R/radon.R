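#' Parallel-beam acquisition geometry
#'
#' Describes a 2-D parallel-beam CT acquisition: `n_angles` (Ma) projection
#' directions equispaced over \[0, pi), `n_detectors` (D) detector bins of
#' unit (pixel) spacing centered on the image center, and the side length of
#' the square reconstruction grid. The total measurement dimension is
#' `m_meas = n_angles * n_detectors`.
#'
#' Conventions: images are indexed `[row, col]`; the detector coordinate at
#' angle 0 is the (centered) column coordinate, so the first sinogram row of
#' an angle-0 acquisition contains column sums of the image.
#'
#' @param n_angles number of projection angles Ma (>= 1).
#' @param n_detectors number of detector bins D (>= 1).
#' @param image_side side length of the square pixel grid (>= 2).
#' @param angles optional vector of angles in radians, strictly increasing,
#'   all in \[0, pi). Defaults to `(0:(Ma-1)) * pi / Ma`.
#' @return Object of class `ct_geometry`.
#' @export
ct_geometry <- function(n_angles, n_detectors, image_side, angles = NULL) {
  stopifnot(n_angles >= 1, n_detectors >= 1, image_side >= 2)
  if (is.null(angles)) angles <- seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)]
  if (length(angles) != n_angles || any(diff(angles) <= 0) ||
      any(angles < 0) || any(angles >= pi))
    stop("angles must be strictly increasing and lie in [0, pi)")
  structure(list(n_angles = as.integer(n_angles),
                 n_detectors = as.integer(n_detectors),
                 image_side = as.integer(image_side),
                 angles = as.numeric(angles)),
            class = "ct_geometry")
}

#' @export
print.ct_geometry <- function(x, ...) {
  cat(sprintf("parallel-beam geometry: Ma = %d angles, D = %d detectors, image %dx%d\n",
              x$n_angles, x$n_detectors, x$image_side, x$image_side))
  invisible(x)
}

#' Paper-scale geometry preset
#'
#' Convenience constructor with the D = 450 detector count used in the
#' reference acquisition setting.
#'
#' @param n_angles number of projection angles.
#' @param image_side image side length.
#' @return A `ct_geometry` with 450 detectors.
#' @export
paper_geometry <- function(n_angles, image_side) {
  ct_geometry(n_angles, 450L, image_side)
}

#' Sinogram container
#' @param values Ma x D numeric matrix of line-integral measurements.
#' @param geometry the `ct_geometry` that produced it.
#' @return Object of class `sinogram`.
#' @export
sinogram <- function(values, geometry) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(geometry$n_angles, geometry$n_detectors)))
    stop(sprintf("sinogram shape %dx%d does not match geometry Ma=%d, D=%d",
                 nrow(values), ncol(values), geometry$n_angles, geometry$n_detectors))
  structure(list(values = values, geometry = geometry), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram %d x %d, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

## Cache of assembled system matrices and their measured norms, keyed by
## geometry. Assembly is vectorized per angle; the adjoint is the exact
## transpose so primal-dual step-size conditions hold without slack.
.radon_cache <- new.env(parent = emptyenv())

.geom_key <- function(geometry) {
  paste(geometry$image_side, geometry$n_detectors,
        paste(signif(geometry$angles, 12), collapse = ","), sep = "|")
}

#' Assemble the sparse Radon system matrix for a geometry
#'
#' Pixel-driven discretization: each pixel center is projected onto the
#' detector axis at every angle and its value is split linearly between the
#' two nearest detector bins (a unit-width strip integral, which approximates
#' the line integral at any angle since detector spacing equals pixel
#' spacing). Rays falling outside the detector range are truncated. The
#' matrix is cached per geometry.
#'
#' @param geometry a [ct_geometry()].
#' @return A `Matrix::sparseMatrix` of dimension `(Ma*D) x N` with row index
#'   `(angle-1)*D + detector` and column index the column-major pixel index.
#' @export
radon_matrix <- function(geometry) {
  key <- .geom_key(geometry)
  hit <- .radon_cache[[key]]
  if (!is.null(hit)) return(hit$A)
  s <- geometry$image_side
  d <- geometry$n_detectors
  half <- (s + 1) / 2
  cc <- rep(seq_len(s), each = s) - half   # column (horizontal) offsets
  rc <- rep(seq_len(s), times = s) - half  # row (vertical) offsets
  pix <- seq_len(s * s)
  ilist <- vector("list", geometry$n_angles)
  jlist <- vector("list", geometry$n_angles)
  xlist <- vector("list", geometry$n_angles)
  for (a in seq_len(geometry$n_angles)) {
    th <- geometry$angles[a]
    pos <- cc * cos(th) + rc * sin(th) + (d + 1) / 2
    k0 <- floor(pos)
    w1 <- 1 - (pos - k0)
    keep0 <- k0 >= 1 & k0 <= d
    keep1 <- (k0 + 1) >= 1 & (k0 + 1) <= d
    ilist[[a]] <- c((a - 1L) * d + k0[keep0], (a - 1L) * d + k0[keep1] + 1L)
    jlist[[a]] <- c(pix[keep0], pix[keep1])
    xlist[[a]] <- c(w1[keep0], (1 - w1)[keep1])
  }
  A <- Matrix::sparseMatrix(i = unlist(ilist), j = unlist(jlist), x = unlist(xlist),
                            dims = c(geometry$n_angles * d, s * s))
  .radon_cache[[key]] <- list(A = A, norm = NULL)
  A
}

#' Forward Radon projection
#'
#' Applies the parallel-beam forward operator to an image.
#'
#' @param image numeric matrix with side `geometry$image_side`.
#' @param geometry a [ct_geometry()].
#' @return A [sinogram()].
#' @export
radon_forward <- function(image, geometry) {
  image <- as.matrix(image)
  if (!all(dim(image) == geometry$image_side))
    stop(sprintf("image is %dx%d but geometry expects %dx%d",
                 nrow(image), ncol(image), geometry$image_side, geometry$image_side))
  A <- radon_matrix(geometry)
  v <- as.numeric(A %*% as.vector(image))
  sinogram(t(matrix(v, nrow = geometry$n_detectors)), geometry)
}

#' Adjoint Radon operator (unfiltered backprojection)
#'
#' Exact numerical adjoint of [radon_forward()] (the transpose of the system
#' matrix), satisfying `<Phi x, u> == <x, Phi' u>` to machine precision.
#'
#' @param sino a [sinogram()].
#' @return image matrix of side `geometry$image_side`.
#' @export
radon_adjoint <- function(sino) {
  geometry <- sino$geometry
  A <- radon_matrix(geometry)
  v <- as.vector(t(sino$values))
  matrix(as.numeric(Matrix::crossprod(A, v)),
         nrow = geometry$image_side, ncol = geometry$image_side)
}

#' Measured operator norm of the Radon operator
#'
#' Power-iteration estimate of `||Phi||`, cached per geometry; deterministic
#' for a fixed geometry (fixed internal probe seed).
#'
#' @param geometry a [ct_geometry()].
#' @return scalar norm estimate.
#' @export
radon_norm <- function(geometry) {
  key <- .geom_key(geometry)
  radon_matrix(geometry)  # ensure cache entry exists
  hit <- .radon_cache[[key]]
  if (!is.null(hit$norm)) return(hit$norm)
  s <- geometry$image_side
  x0 <- withr::with_seed(421L, matrix(stats::rnorm(s * s), s, s))
  op <- linear_op(function(x) radon_forward(x, geometry)$values,
                  function(u) radon_adjoint(sinogram(u, geometry)),
                  norm_bound = Inf, name = "radon")
  nrm <- estimate_op_norm(op, x0, iters = 200, tol = 1e-8)
  hit$norm <- nrm
  .radon_cache[[key]] <- hit
  nrm
}

#' Counted Radon linear operator
#'
#' Wraps forward/adjoint projection for a geometry as a [linear_op()] with
#' fresh application counters. The norm bound is the power-iteration estimate
#' inflated by 0.5% so the bound provably dominates it.
#'
#' @param geometry a [ct_geometry()].
#' @return a [linear_op()] mapping images to Ma x D sinogram value matrices.
#' @export
radon_op <- function(geometry) {
  nb <- radon_norm(geometry) * 1.005
  # capture the assembled matrix once: solver-time applications must not
  # pay the cache lookup or container validation
  A <- radon_matrix(geometry)
  d <- geometry$n_detectors
  s <- geometry$image_side
  linear_op(function(x) t(matrix(as.numeric(A %*% as.vector(x)), nrow = d)),
            function(u) matrix(as.numeric(Matrix::crossprod(A, as.vector(t(u)))),
                               nrow = s, ncol = s),
            norm_bound = nb, name = "Phi")
}

#' Simulate noisy CT measurements
#'
#' `y = Phi x + w` with `w` i.i.d. zero-mean Gaussian. The noise level can be
#' given in absolute sinogram units, or — the convention used by the phantom
#' scenarios — as a fraction of the maximum absolute value of the noiseless
#' sinogram, which transfers the reference noise regimes (sigma 0.007–0.175)
#' onto synthetic sinograms of arbitrary dynamic range.
#'
#' @param image ground-truth image matrix.
#' @param geometry a [ct_geometry()].
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed; the draw is deterministic given the seed and
#'   does not disturb the global RNG stream.
#' @param relative if `TRUE`, `sigma` is interpreted as a fraction of
#'   `max(abs(Phi x))`.
#' @return a [sinogram()] with attribute `sigma_abs`, the absolute noise
#'   standard deviation actually applied.
#' @export
simulate_measurements <- function(image, geometry, sigma, seed, relative = FALSE) {
  stopifnot(sigma >= 0)
  clean <- radon_forward(image, geometry)
  sig_abs <- if (relative) sigma * max(abs(clean$values)) else sigma
  vals <- clean$values
  if (sig_abs > 0) {
    w <- withr::with_seed(as.integer(seed),
                          stats::rnorm(length(vals), sd = sig_abs))
    vals <- vals + matrix(w, nrow = nrow(vals))
  }
  out <- sinogram(vals, geometry)
  attr(out, "sigma_abs") <- sig_abs
  out
}

#' High-probability bound on the noise energy
#'
#' Radius `eps` such that `P(||w||_2 <= eps) = quantile` for an i.i.d.
#' Gaussian vector of length `m_meas` and standard deviation `sigma`:
#' `sigma * sqrt(qchisq(quantile, m_meas))`. Used as the data-fidelity ball
#' radius, making the constraint feasible with probability `quantile`.
#'
#' @param sigma noise standard deviation.
#' @param m_meas measurement dimension `Ma * D`.
#' @param quantile coverage probability in (0, 1); default 0.99.
#' @return scalar radius.
#' @export
epsilon_bound <- function(sigma, m_meas, quantile = 0.99) {
  stopifnot(quantile > 0, quantile < 1, sigma >= 0, m_meas >= 1)
  sigma * sqrt(stats::qchisq(quantile, df = m_meas))
}
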