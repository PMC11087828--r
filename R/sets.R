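#' Sparsity budget of the conservative credible region
#'
#' The conservative (1 - alpha) credible region is the set of nonnegative
#' images satisfying the data-fidelity ball and an l1 analysis budget
#' `||Psi x||_1 <= eta_alpha` anchored at the MAP estimate. The default
#' budget is
#' \deqn{\eta_\alpha = \|\Psi x^\dagger\|_1 + N + \sqrt{16 N \log(3/\alpha)},}
#' the square-root-of-N concentration form of the conservative credible
#' region bound. The `"verbatim"` reading with the linear term
#' `16 N log(3/alpha)` is also available; both only rescale the budget.
#' The budget is strictly decreasing in `alpha` and always at least
#' `psi_l1_of_map + n_pixels`, so the MAP estimate is never excluded.
#'
#' @param psi_l1_of_map `||Psi x_dagger||_1` of the MAP estimate.
#' @param n_pixels image dimension N.
#' @param alpha significance level in (0, 1).
#' @param reading `"radical"` (default) or `"verbatim"`.
#' @return scalar budget `eta_alpha`.
#' @export
compute_eta_alpha <- function(psi_l1_of_map, n_pixels, alpha,
                              reading = c("radical", "verbatim")) {
  reading <- match.arg(reading)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  stopifnot(n_pixels >= 1, psi_l1_of_map >= 0)
  slack <- 16 * n_pixels * log(3 / alpha)
  psi_l1_of_map + n_pixels + if (reading == "radical") sqrt(slack) else slack
}

#' Conservative credible region
#'
#' Container for `C_alpha = {x >= 0 : ||Phi x - y||_2 <= epsilon,
#' ||Psi x||_1 <= eta_alpha}`.
#'
#' @param y measurement [sinogram()].
#' @param epsilon data-fidelity radius used for the MAP estimate.
#' @param eta_alpha l1 analysis budget from [compute_eta_alpha()].
#' @param alpha significance level in (0, 1).
#' @param psi the [psi_spec()] used for the MAP estimate.
#' @param geometry acquisition geometry.
#' @return Object of class `credible_region`.
#' @export
credible_region <- function(y, epsilon, eta_alpha, alpha, psi, geometry = y$geometry) {
  stopifnot(inherits(y, "sinogram"), epsilon >= 0, eta_alpha >= 0,
            alpha > 0, alpha < 1, inherits(psi, "psi_spec"))
  structure(list(y = y, epsilon = epsilon, eta_alpha = eta_alpha,
                 alpha = alpha, psi = psi, geometry = geometry),
            class = "credible_region")
}

#' Binary-mask dilation
#'
#' Morphological dilation by a disc brush (EBImage), used to carve the
#' sampling annulus around a candidate structure.
#'
#' @param mask logical matrix.
#' @param width dilation radius in pixels (>= 1).
#' @return logical matrix of the dilated mask.
#' @export
dilate_mask <- function(mask, width) {
  stopifnot(width >= 1)
  sz <- 2L * as.integer(width) + 1L
  brush <- EBImage::makeBrush(sz, shape = "disc")
  EBImage::dilate(mask * 1, brush) > 0.5
}

#' Structure-absent set for a candidate region
#'
#' Builds the convex set S of images in which the candidate structure is
#' absent, as the intersection of three sets: the nonnegative orthant
#' (intensity), an energy ball forcing the masked pixels close to the
#' neighborhood's typical intensity, and a smoothness ball forcing the masked
#' gradient close to the neighborhood's typical variation.
#'
#' The target/radius pairs are chosen automatically from histograms over a
#' sampling annulus (the mask dilated by `dilation_width`, minus the mask,
#' optionally intersected with a body mask): `mu_pix` is the median of the
#' annulus intensities and `r_pix = max(P60 - median, median - P40)` under
#' the linear-interpolation percentile convention (`stats::quantile` type 7);
#' `mu_grad`, `r_grad` are computed identically from the histogram of the
#' sampled gradients — the signed finite-difference components of both
#' channels over the annulus. (In a homogeneous neighborhood this centers
#' the smoothness ball near zero, which is what "no structure" means for
#' the masked gradient; centering it at a positive magnitude would demand a
#' spurious intensity ramp inside the mask.) The l2-ball radii used in the constraints are scaled by the
#' square root of the number of constrained components (`r_pix * sqrt(NS)`;
#' `r_grad * sqrt(2 NS)`), so the radii are per-pixel RMS bounds independent
#' of the mask size.
#'
#' A reconstruction with a piecewise-flat neighborhood can drive the
#' percentile spreads to zero (or to floating-point dust), leaving balls
#' tighter than any solver tolerance; the radii are therefore floored at
#' `r_floor_frac` of the reconstruction's dynamic range — numerically
#' benign, scientifically indistinguishable from exact matching.
#'
#' @param x_dagger MAP estimate image.
#' @param mask logical matrix selecting the candidate structure (nonempty).
#' @param dilation_width annulus width in pixels (default 3).
#' @param within optional logical matrix (e.g. body mask); annulus samples
#'   are restricted to it.
#' @param r_floor_frac radius floor as a fraction of `diff(range(x_dagger))`
#'   (default 1e-3).
#' @return Object of class `structure_set` with fields `mask`,
#'   `neighborhood`, `mu_pix`, `r_pix`, `mu_grad`, `r_grad`, `n_s`.
#' @export
build_structure_set <- function(x_dagger, mask, dilation_width = 3,
                                within = NULL, r_floor_frac = 1e-3) {
  mask <- mask > 0
  if (!any(mask)) stop("structure mask is empty")
  nb <- dilate_mask(mask, dilation_width) & !mask
  if (!is.null(within)) nb <- nb & (within > 0)
  if (!any(nb)) stop("sampling neighborhood is empty (mask touches the allowed region boundary?)")
  vals <- x_dagger[nb]
  mu_pix <- stats::median(vals)
  q <- stats::quantile(vals, c(0.4, 0.6), names = FALSE, type = 7)
  r_pix <- max(q[2] - mu_pix, mu_pix - q[1])
  g <- grad2d(x_dagger)
  gv <- c(g[, , 1][nb], g[, , 2][nb])  # signed components, both channels
  mu_grad <- stats::median(gv)
  qg <- stats::quantile(gv, c(0.4, 0.6), names = FALSE, type = 7)
  r_grad <- max(qg[2] - mu_grad, mu_grad - qg[1])
  r_floor <- r_floor_frac * (max(x_dagger) - min(x_dagger))
  r_pix <- max(r_pix, r_floor)
  r_grad <- max(r_grad, r_floor)
  # reference scales of the constrained quantities (used to measure
  # constraint violations on the problem's own scale, not a degenerate
  # radius's)
  scale_pix <- sqrt(sum(x_dagger[mask]^2))
  gm <- g[, , 1][mask]; gm2 <- g[, , 2][mask]
  scale_grad <- sqrt(sum(gm^2) + sum(gm2^2))
  structure(list(mask = mask, neighborhood = nb,
                 mu_pix = mu_pix, r_pix = r_pix,
                 mu_grad = mu_grad, r_grad = r_grad,
                 n_s = sum(mask),
                 scale_pix = scale_pix, scale_grad = scale_grad),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf(paste0("structure-absent set: %d masked pixels, %d annulus samples\n",
                     "  intensity mu = %.4g (r = %.4g), gradient mu = %.4g (r = %.4g)\n"),
              x$n_s, sum(x$neighborhood), x$mu_pix, x$r_pix, x$mu_grad, x$r_grad))
  invisible(x)
}

## mask-selection operator M and its composition with the gradient

mask_select_op <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  linear_op(function(x) x[idx],
            function(v) { out <- matrix(0, nr, nc); out[idx] <- v; out },
            norm_bound = 1, name = "mask")
}

mask_grad_op <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  linear_op(function(x) { g <- grad2d(x); c(g[, , 1][idx], g[, , 2][idx]) },
            function(v) {
              ns <- length(idx)
              g <- array(0, dim = c(nr, nc, 2))
              g1 <- matrix(0, nr, nc); g1[idx] <- v[seq_len(ns)]
              g2 <- matrix(0, nr, nc); g2[idx] <- v[ns + seq_len(ns)]
              g[, , 1] <- g1; g[, , 2] <- g2
              div2d_adjoint(g)
            },
            norm_bound = sqrt(8), name = "mask_grad")
}

## Effective l2-ball radii for the energy and smoothness constraints.
.sset_radii <- function(s) {
  list(pix = s$r_pix * sqrt(s$n_s), grad = s$r_grad * sqrt(2 * s$n_s))
}

## Violation scales: the larger of the ball's radius, its center norm, and
## the reference magnitude of the constrained quantity.
.sset_scales <- function(s) {
  rr <- .sset_radii(s)
  ref_pix <- if (is.null(s$scale_pix)) 0 else s$scale_pix
  ref_grad <- if (is.null(s$scale_grad)) 0 else s$scale_grad
  list(pix = max(rr$pix, abs(s$mu_pix) * sqrt(s$n_s), ref_pix,
                 .Machine$double.eps),
       grad = max(rr$grad, abs(s$mu_grad) * sqrt(2 * s$n_s), ref_grad,
                  .Machine$double.eps))
}

#' Membership of an image in a constraint set
#'
#' Checks every constraint of a [credible_region()] or a `structure_set`
#' within a relative tolerance and reports each constraint's violation
#' magnitude (relative distance to the constraint set, 0 when satisfied).
#'
#' @param x image matrix.
#' @param region a `credible_region` or `structure_set`.
#' @param tol relative tolerance (default 1e-4).
#' @param ... passed to methods; `membership.credible_region` accepts
#'   `Phix`, a precomputed forward projection of `x` (so callers can route
#'   the application through a counted operator).
#' @return list with `member` (logical) and `violations` (named numeric).
#' @export
membership <- function(x, region, tol = 1e-4, ...) UseMethod("membership", region)

#' @rdname membership
#' @export
membership.credible_region <- function(x, region, tol = 1e-4, ..., Phix = NULL) {
  if (is.null(Phix)) Phix <- radon_forward(x, region$geometry)$values
  psio <- psi_op(region$psi, region$geometry$image_side)
  v <- c(intensity = .feas_nonneg()(x),
         data_ball = .feas_l2_ball(region$y$values, region$epsilon)(Phix),
         psi_budget = .feas_l1_ball(region$eta_alpha)(psio$forward(x)))
  list(member = all(v <= tol), violations = v)
}

#' @rdname membership
#' @export
membership.structure_set <- function(x, region, tol = 1e-4, ...) {
  rr <- .sset_radii(region)
  sc <- .sset_scales(region)
  mv <- x[region$mask]
  g <- grad2d(x)
  gv <- c(g[, , 1][region$mask], g[, , 2][region$mask])
  v <- c(intensity = .feas_nonneg()(x),
         energy = .feas_l2_ball(rep(region$mu_pix, region$n_s), rr$pix,
                                scale = sc$pix)(mv),
         smoothness = .feas_l2_ball(rep(region$mu_grad, 2 * region$n_s), rr$grad,
                                    scale = sc$grad)(gv))
  list(member = all(v <= tol), violations = v)
}

## Dualized constraint terms for a structure set acting on an image-valued
## expression `extract(z)` of the solver iterate (identity for plain images,
## a block selector on product spaces).
.sset_terms <- function(s, lift = identity) {
  rr <- .sset_radii(s)
  mop <- mask_select_op(s$mask)
  gop <- mask_grad_op(s$mask)
  ns <- s$n_s
  gn <- .unit_op(gop)
  sc <- .sset_scales(s)
  ctr_pix <- rep(s$mu_pix, ns)
  ctr_grad <- rep(s$mu_grad, 2 * ns) / gn$scale
  r_grad_n <- rr$grad / gn$scale
  list(
    pd_term(lift(identity_image_op(dim(s$mask)[1], dim(s$mask)[2])),
            prox = function(v, tau) project_nonneg(v),
            feas = .feas_nonneg(), name = "intensity"),
    pd_term(lift(mop),
            prox = function(v, tau) project_l2_ball(v, ctr_pix, rr$pix),
            feas = .feas_l2_ball(ctr_pix, rr$pix, scale = sc$pix),
            name = "energy"),
    pd_term(lift(gn$op),
            prox = function(v, tau) project_l2_ball(v, ctr_grad, r_grad_n),
            feas = .feas_l2_ball(ctr_grad, r_grad_n, scale = sc$grad / gn$scale),
            name = "smoothness"))
}

identity_image_op <- function(nr, nc) {
  linear_op(function(x) x, function(u) u, norm_bound = 1, name = "id")
}

#' Euclidean projection onto the structure-absent set
#'
#' Computes `Proj_S(x)` — the closest image to `x` in the intersection of
#' the intensity, energy and smoothness sets — by primal-dual splitting with
#' `f = 0.5 ||. - x||^2`. Pixels outside the mask and the gradient stencil
#' around it are untouched up to solver tolerance.
#'
#' @param x image matrix.
#' @param s a `structure_set` from [build_structure_set()].
#' @param config a [solver_config()].
#' @return projected image with attributes `converged` and `iterations`.
#' @export
project_structure_set <- function(x, s, config = solver_config()) {
  stopifnot(inherits(s, "structure_set"))
  sol <- primal_dual_solve(function(v, tau) (v + tau * x) / (1 + tau),
                           .sset_terms(s), x, config)
  out <- sol$x
  attr(out, "converged") <- sol$converged
  attr(out, "iterations") <- sol$iterations
  attr(out, "duals") <- sol$duals
  out
}
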