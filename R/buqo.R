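## The hypothesis test: distance between the structure-absent set S and the
## conservative credible region C_alpha, the structure-confidence statistic,
## and the end-to-end pipeline.

## lift an image-domain linear op onto one block of the (xS, xC) product
.block_lift <- function(block, template) {
  force(block)
  zt <- vs_zero_like(template)
  function(op) {
    # route through the counted interface so the wrapped operator's
    # application counters keep accounting for cost
    linear_op(function(z) op_apply(op, z[[block]]),
              function(u) {
                out <- zt
                out[[block]] <- op_apply_adjoint(op, u)
                out
              },
              norm_bound = op$norm_bound,
              name = paste0(block, ":", op$name))
  }
}

#' Set distance between the credible region and the structure-absent set
#'
#' Two-stage test. Stage 1 projects the MAP estimate onto the
#' structure-absent set S; if that projection already lies in the credible
#' region `C_alpha`, the two sets intersect and the distance is zero (early
#' exit). Otherwise stage 2 jointly minimizes `0.5 ||xC - xS||^2` over
#' `xS in S`, `xC in C_alpha` by a single primal-dual run on the product
#' space, warm-started at `(Proj_S(x_dagger), x_dagger)`, and returns the
#' closest pair. Forward-operator applications across both stages (stage 1
#' uses none; the stage-1 membership check uses one) are counted in
#' `op_evals`.
#'
#' @param x_dagger MAP estimate image.
#' @param cred a [credible_region()] built from the same data, radius and
#'   transform as `x_dagger`.
#' @param s a `structure_set` from [build_structure_set()].
#' @param config a [solver_config()].
#' @param force_stage2 run stage 2 even when stage 1 exits early (debug /
#'   consistency checks).
#' @param map_duals optional `duals` element of a [map_estimate()] result;
#'   when given, stage 2 warm-starts its data-ball dual from the
#'   reconstruction's, which keeps the credible-region side near-feasible
#'   throughout and shortens the solve considerably.
#' @param delta decision tolerance on the confidence statistic; stage 2
#'   stops once the feasible pair's distance drops below `delta` times the
#'   distance from the MAP estimate to its structure-removed projection
#'   (the conclusion can no longer change).
#' @return list with `x_hat_S`, `x_hat_C`, `x_dagger_S`, `dist`,
#'   `early_exit`, `converged`, `op_evals`, `iterations`, `stage1_member`.
#' @export
buqo_distance <- function(x_dagger, cred, s, config = solver_config(),
                          force_stage2 = FALSE, map_duals = NULL,
                          delta = 1e-3) {
  stopifnot(inherits(cred, "credible_region"), inherits(s, "structure_set"))
  phi <- radon_op(cred$geometry)
  psio <- psi_op(cred$psi, cred$geometry$image_side)

  xds <- project_structure_set(x_dagger, s, config)
  stage1_conv <- isTRUE(attr(xds, "converged"))
  mem <- membership(xds, cred, tol = config$tol_feas,
                    Phix = op_apply(phi, xds))

  if (mem$member && !force_stage2) {
    return(list(x_hat_S = xds, x_hat_C = xds, x_dagger_S = xds, dist = 0,
                early_exit = TRUE, converged = stage1_conv,
                op_evals = sum(op_counts(phi)),
                iterations = attr(xds, "iterations"),
                stage1_member = mem))
  }

  template <- list(xS = x_dagger, xC = x_dagger)
  lift_S <- .block_lift("xS", template)
  lift_C <- .block_lift("xC", template)

  phin <- .unit_op(phi)
  psin <- .unit_op(psio)
  yn <- cred$y$values / phin$scale
  epsn <- cred$epsilon / phin$scale
  etan <- cred$eta_alpha / psin$scale
  terms <- c(.sset_terms(s, lift = lift_S),
             list(
               pd_term(lift_C(identity_image_op(nrow(x_dagger), ncol(x_dagger))),
                       prox = function(v, tau) project_nonneg(v),
                       feas = .feas_nonneg(), name = "C_intensity"),
               pd_term(lift_C(phin$op),
                       prox = function(v, tau) project_l2_ball(v, yn, epsn),
                       feas = .feas_l2_ball(yn, epsn),
                       name = "C_data_ball"),
               pd_term(lift_C(psin$op),
                       prox = function(v, tau) project_l1_ball(v, etan),
                       feas = .feas_l1_ball(etan),
                       name = "C_psi_budget")))

  ## prox of tau/2 ||xC - xS||^2, jointly in (xS, xC): closed form
  couple_prox <- function(z, tau) {
    d <- (z$xC - z$xS) * (tau / (1 + 2 * tau))
    list(xS = z$xS + d, xC = z$xC - d)
  }

  ## warm duals: the S-side terms from the stage-1 projection; the data
  ## ball from the reconstruction (rescaled for the normalized operator);
  ## the psi budget starts at zero (eta_alpha leaves it inactive at x†)
  s1d <- attr(xds, "duals")
  init_duals <- c(
    if (!is.null(s1d)) s1d else list(x_dagger * 0,
                                     rep(0, s$n_s), rep(0, 2 * s$n_s)),
    list(x_dagger * 0,
         if (!is.null(map_duals)) map_duals$data * phin$scale
         else cred$y$values * 0,
         psio$forward(x_dagger) * 0))

  ## decision-resolution floor: once the pair is feasible and its distance
  ## is below delta times the structure scale, rho_alpha <= delta no matter
  ## how much further the solve is refined, so the conclusion is fixed
  den0 <- sqrt(sum((x_dagger - xds)^2))
  sol <- primal_dual_solve(couple_prox, terms,
                           list(xS = xds, xC = x_dagger), config,
                           init_duals = init_duals,
                           progress = function(z) sqrt(sum((z$xC - z$xS)^2)),
                           progress_floor = delta * den0)
  xS <- sol$x$xS; xC <- sol$x$xC
  list(x_hat_S = xS, x_hat_C = xC, x_dagger_S = xds,
       dist = sqrt(sum((xC - xS)^2)),
       early_exit = FALSE,
       converged = stage1_conv && sol$converged,
       op_evals = sum(op_counts(phi)),
       iterations = sol$iterations,
       stage1_member = mem, history = sol$history)
}

#' Structure-confidence statistic
#'
#' The achieved set distance normalized by the distance from the MAP
#' estimate to its structure-removed projection:
#' \deqn{\rho_\alpha = \|\hat{x}_C - \hat{x}_S\|_2 / \|x^\dagger - x^\dagger_S\|_2 \in [0, 1].}
#' Interpretable as the fraction of the structure's energy that the data
#' confirm. Clipped to \[0, 1\] against float overshoot; if the MAP estimate
#' is already structure-free (zero denominator) the statistic is 0 by
#' convention.
#'
#' @param x_hat_C,x_hat_S closest pair from [buqo_distance()].
#' @param x_dagger MAP estimate.
#' @param x_dagger_S its projection onto the structure-absent set.
#' @return scalar in \[0, 1\].
#' @export
structure_confidence <- function(x_hat_C, x_hat_S, x_dagger, x_dagger_S) {
  den <- sqrt(sum((x_dagger - x_dagger_S)^2))
  if (den == 0) return(0)
  num <- sqrt(sum((x_hat_C - x_hat_S)^2))
  min(max(num / den, 0), 1)
}

#' Decision rule
#'
#' Rejects the null hypothesis (structure absent) iff the structure
#' confidence exceeds the numerical tolerance `delta`; the boundary
#' `rho_alpha == delta` goes to the null.
#'
#' @param rho_alpha structure confidence in \[0, 1\].
#' @param delta user tolerance in \[0, 1).
#' @return `"REJECT_H0"` or `"CANNOT_REJECT"`.
#' @export
decide <- function(rho_alpha, delta = 1e-3) {
  stopifnot(delta >= 0, delta < 1)
  if (rho_alpha > delta) "REJECT_H0" else "CANNOT_REJECT"
}

#' End-to-end structure uncertainty test on a scenario
#'
#' Orchestrates the full pipeline: simulate measurements for the scenario,
#' reconstruct the MAP estimate, build the conservative credible region and
#' the structure-absent set around the probe mask, compute the set distance,
#' the structure confidence and the decision. The cost of the
#' uncertainty-quantification stage relative to the reconstruction is
#' reported as the ratio of forward-operator evaluation counts.
#'
#' @param scenario a `ct_scenario` from [make_pe_scenario()] or
#'   [make_artifact_scenario()].
#' @param alpha significance level (default 0.01).
#' @param delta decision tolerance (default 1e-3).
#' @param psi a [psi_spec()] (default TV).
#' @param quantile coverage of the noise-energy bound (default 0.99).
#' @param dilation_width annulus width for the structure set (default 3).
#' @param map_config,buqo_config solver configurations for the two stages.
#' @return Object of class `buqo_test` containing `map` (the
#'   [map_estimate()] result), `buqo` (the [buqo_distance()] output),
#'   `rho_alpha`, `decision` (`NA` if any solver failed to converge),
#'   `cost_ratio`, `eta_alpha`, `epsilon`, `sset`, `cred`, and the scenario.
#' @export
run_test <- function(scenario, alpha = 0.01, delta = 1e-3,
                     psi = psi_spec("tv"), quantile = 0.99,
                     dilation_width = 3,
                     map_config = solver_config(),
                     buqo_config = map_config) {
  stopifnot(inherits(scenario, "ct_scenario"))
  geom <- scenario$geometry
  ph <- scenario$phantom
  y <- simulate_measurements(ph$image, geom, scenario$sigma,
                             seed = scenario$noise_seed, relative = TRUE)
  sig_abs <- attr(y, "sigma_abs")
  m_meas <- geom$n_angles * geom$n_detectors
  epsilon <- if (sig_abs > 0) epsilon_bound(sig_abs, m_meas, quantile)
             else 1e-4 * sqrt(sum(y$values^2))
  # artifact scenarios carry the reconstruction they were detected on;
  # reuse it when it matches this run's settings (identical by determinism)
  cache <- attr(scenario, "map_cache")
  mp <- if (!is.null(cache) && identical(cache$psi, psi) &&
            isTRUE(all.equal(cache$epsilon, epsilon))) cache
        else map_estimate(y, geom, psi = psi, epsilon = epsilon,
                          config = map_config)
  n_pix <- geom$image_side^2
  eta <- compute_eta_alpha(mp$psi_l1, n_pix, alpha)
  cred <- credible_region(y, epsilon, eta, alpha, psi, geom)
  # sample the annulus inside the enclosing vessel when the phantom provides
  # its outline (the stand-in for the radiologist sampling the surrounding
  # arterial lumen); otherwise fall back to the body
  within <- if (!is.null(ph$vessel_mask) && any(ph$vessel_mask)) ph$vessel_mask
            else ph$body_mask
  sset <- build_structure_set(mp$x_dagger, scenario$probe_mask,
                              dilation_width = dilation_width,
                              within = within)
  bq <- buqo_distance(mp$x_dagger, cred, sset, config = buqo_config,
                      map_duals = mp$duals, delta = delta)
  rho <- structure_confidence(bq$x_hat_C, bq$x_hat_S, mp$x_dagger, bq$x_dagger_S)
  ok <- mp$converged && bq$converged
  structure(list(scenario = scenario, map = mp, buqo = bq,
                 rho_alpha = rho,
                 decision = if (ok) decide(rho, delta) else NA_character_,
                 delta = delta, alpha = alpha,
                 epsilon = epsilon, eta_alpha = eta,
                 cred = cred, sset = sset,
                 cost_ratio = bq$op_evals / mp$op_evals,
                 converged = ok),
            class = "buqo_test")
}

#' @export
print.buqo_test <- function(x, ...) {
  cat(sprintf(paste0("structure uncertainty test [%s scenario]\n",
                     "  rho_alpha = %.4g, decision: %s%s\n",
                     "  set distance %.4g (early exit: %s)\n",
                     "  cost: %d UQ vs %d reconstruction operator evals (ratio %.3f)\n"),
              x$scenario$truth, x$rho_alpha,
              if (is.na(x$decision)) "none (solver not converged)" else x$decision,
              sprintf(" (delta = %.1e)", x$delta),
              x$buqo$dist, x$buqo$early_exit,
              x$buqo$op_evals, x$map$op_evals, x$cost_ratio))
  invisible(x)
}
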