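#' Sparsifying transform specification
#'
#' The analysis operator Psi whose l1 norm is minimized by the MAP
#' reconstruction. `"tv"` (default) is the anisotropic total-variation
#' analysis operator, i.e. the finite-difference gradient of [grad2d()];
#' `"wavelet"` is the orthonormal multilevel Haar transform.
#'
#' @param kind `"tv"` or `"wavelet"`.
#' @param levels wavelet decomposition levels (wavelet kind only).
#' @return Object of class `psi_spec`.
#' @export
psi_spec <- function(kind = c("tv", "wavelet"), levels = 3L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, levels = as.integer(levels)), class = "psi_spec")
}

#' Analysis operator for a sparsity specification
#'
#' Instantiates Psi as a counted [linear_op()] on a given image side. The TV
#' operator has norm bound `sqrt(8)`; the orthonormal Haar transform has norm
#' exactly 1.
#'
#' @param psi a [psi_spec()].
#' @param image_side side of the square image domain.
#' @return a [linear_op()].
#' @export
psi_op <- function(psi, image_side) {
  stopifnot(inherits(psi, "psi_spec"))
  if (psi$kind == "tv") {
    grad_op(image_side)
  } else {
    lv <- psi$levels
    if (image_side %% (2^lv) != 0)
      stop("wavelet levels incompatible with image side")
    linear_op(function(x) haar_analysis(x, lv),
              function(w) haar_synthesis(w, lv),
              norm_bound = 1, name = "Psi")
  }
}

#' Constrained MAP reconstruction
#'
#' Computes the maximum-a-posteriori estimate under an l1 analysis sparsity
#' prior and a hard data-fidelity constraint:
#' \deqn{x^\dagger = \arg\min_{x \ge 0} \|\Psi x\|_1
#'       \quad \mathrm{s.t.} \quad \|\Phi x - y\|_2 \le \epsilon,}
#' solved by primal-dual proximal splitting. Nonnegativity is enforced so
#' that the estimate lies in the conservative credible region built around
#' it. Initialization is the scaled backprojection
#' `Phi' y / ||Phi||^2` (deterministic, geometry-agnostic).
#'
#' @param y a [sinogram()] of measurements.
#' @param geometry acquisition geometry; defaults to `y$geometry`.
#' @param psi a [psi_spec()]; default anisotropic TV.
#' @param epsilon data-fidelity ball radius (>= 0), typically from
#'   [epsilon_bound()].
#' @param config a [solver_config()].
#' @return Object of class `map_result` with fields `x_dagger` (image),
#'   `epsilon`, `psi_l1` (`||Psi x||_1`), `data_residual`
#'   (`||Phi x - y||_2`), `converged`, `iterations`, `op_evals` (total
#'   forward + adjoint applications of Phi), and `history`.
#' @export
map_estimate <- function(y, geometry = y$geometry, psi = psi_spec("tv"),
                         epsilon, config = solver_config()) {
  stopifnot(inherits(y, "sinogram"), epsilon >= 0)
  s <- geometry$image_side
  phi <- radon_op(geometry)
  psio <- psi_op(psi, s)

  # the data ball is the stiff constraint here: keep Phi un-normalized so
  # the norm-proportional dual allocation concentrates on enforcing it
  t_data <- pd_term(phi,
                    prox = function(v, tau) project_l2_ball(v, y$values, epsilon),
                    feas = .feas_l2_ball(y$values, epsilon),
                    name = "data_ball")
  t_psi <- pd_term(psio,
                   prox = function(v, tau) soft_threshold(v, tau),
                   feas = NULL, name = "psi_l1")

  init <- op_apply_adjoint(phi, y$values) / phi$norm_bound^2
  sol <- primal_dual_solve(function(v, tau) project_nonneg(v),
                           list(t_data, t_psi), init, config)

  xd <- sol$x
  resid <- sqrt(sum((op_apply(phi, xd) - y$values)^2))
  psil1 <- sum(abs(psio$forward(xd)))
  structure(list(x_dagger = xd, epsilon = epsilon, psi_l1 = psil1,
                 data_residual = resid, converged = sol$converged,
                 iterations = sol$iterations,
                 op_evals = sum(op_counts(phi)),
                 psi = psi, geometry = geometry, history = sol$history,
                 duals = list(data = sol$duals[[1]], psi = sol$duals[[2]])),
            class = "map_result")
}

#' @export
print.map_result <- function(x, ...) {
  cat(sprintf(paste0("MAP reconstruction: %dx%d image, ||Psi x||_1 = %.4g, ",
                     "residual %.4g (eps = %.4g)\n  %s after %d iterations, ",
                     "%d forward-operator evaluations\n"),
              nrow(x$x_dagger), ncol(x$x_dagger), x$psi_l1, x$data_residual,
              x$epsilon, if (x$converged) "converged" else "NOT converged",
              x$iterations, x$op_evals))
  invisible(x)
}
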