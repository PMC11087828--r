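#' Solver configuration
#'
#' Tolerances and iteration limits shared by the reconstruction and
#' set-distance solvers. Convergence is declared when every constraint is
#' satisfied to `tol_feas` (relative distance-to-set) and the iterate's
#' relative change drops below `tol_primal`.
#'
#' @param max_iters iteration cap; non-convergence within the cap is flagged,
#'   never silently ignored.
#' @param tol_primal relative-change tolerance on the primal iterate.
#' @param tol_feas relative constraint-violation tolerance.
#' @param step_scale safety factor in (0, 1) applied to the primal-dual
#'   step-size condition `tau * sum_i sigma_i ||L_i||^2 <= 1`.
#' @param check_every convergence (and feasibility) check interval in
#'   iterations; feasibility checks cost one extra forward application per
#'   constraint.
#' @param relax over-relaxation factor in (0, 2); values near 2 typically
#'   shorten the feasibility tail of the iteration.
#' @param verbose print residuals at every check.
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(max_iters = 20000L, tol_primal = 1e-5,
                          tol_feas = 1e-4, step_scale = 0.95,
                          check_every = 25L, relax = 1.8, verbose = FALSE) {
  stopifnot(max_iters >= 1, tol_primal > 0, tol_feas > 0,
            step_scale > 0, step_scale < 1, check_every >= 1,
            relax > 0, relax < 2)
  structure(list(max_iters = as.integer(max_iters), tol_primal = tol_primal,
                 tol_feas = tol_feas, step_scale = step_scale,
                 check_every = as.integer(check_every), relax = relax,
                 verbose = verbose),
            class = "solver_config")
}

#' Dualized term for the primal-dual solver
#'
#' Represents one summand `g_i(L_i x)` of the composite objective. For
#' constraint sets `g_i` is an indicator and `prox` is the projection onto
#' the set (ignoring its second argument); `feas` then measures the relative
#' distance of a point to the set so the solver can monitor feasibility.
#' Non-indicator terms (e.g. an l1 norm) supply their proximity operator
#' `prox(v, tau) = prox_{tau * g}(v)` and leave `feas` as `NULL`.
#'
#' @param op a [linear_op()] `L_i`.
#' @param prox function `(v, tau)` returning `prox_{tau*g_i}(v)`.
#' @param feas optional function of `L_i x` returning a relative violation
#'   (0 when satisfied); `NULL` for non-constraint terms.
#' @param name label for diagnostics.
#' @return Object of class `pd_term`.
#' @export
pd_term <- function(op, prox, feas = NULL, name = "term") {
  stopifnot(inherits(op, "linear_op"), is.function(prox))
  structure(list(op = op, prox = prox, feas = feas, name = name),
            class = "pd_term")
}

#' Generic primal-dual proximal splitting solver
#'
#' Solves `min_x f(x) + sum_i g_i(L_i x)` with `f` given by its proximity
#' operator and every `g_i` dualized (Condat--Vu / PDHG family):
#' \preformatted{
#'   x_{k+1}   = prox_{tau f}( x_k - tau * sum_i L_i' u_i^k )
#'   xbar      = 2 x_{k+1} - x_k
#'   u_i^{k+1} = (I - sigma_i prox_{g_i / sigma_i}(. / sigma_i)) (u_i^k + sigma_i L_i xbar)
#' }
#' Step sizes are derived from the terms' norm bounds with the safety factor
#' of the configuration, so `tau * sum_i sigma_i ||L_i||^2 < 1`. Iterates may
#' live on a product space (named lists of arrays), which is how the joint
#' set-distance problem over two image copies is solved.
#'
#' @param f_prox function `(v, tau)` returning `prox_{tau f}(v)`; use
#'   `function(v, tau) v` for `f = 0`.
#' @param terms list of [pd_term()] objects.
#' @param init initial iterate (image matrix or named list of arrays).
#' @param config a [solver_config()].
#' @param init_duals optional list of dual starting points (one per term,
#'   codomain-shaped); warm-starting duals from a related solve keeps the
#'   iterates near-feasible from the first iteration.
#' @param progress optional function of the iterate returning the scalar
#'   estimate the caller is solving for (e.g. a set distance); recorded in
#'   the history at every check.
#' @param progress_floor optional resolution floor: once the iterate is
#'   feasible and the `progress` summary is at or below this value, the
#'   solve is declared converged (used when further refinement cannot
#'   change the caller's conclusion).
#' @param progress_scale scale for relative drift of the `progress` summary.
#' @param progress_patience if > 0, the solve is also declared converged
#'   once the iterate is feasible and the per-iteration relative drift of
#'   the `progress` summary has stayed below `tol_primal` for this many
#'   consecutive checks — the estimate has stabilized even if the witness
#'   iterate still slides tangentially along the constraint boundaries.
#' @return list with elements `x` (final iterate), `converged` (logical),
#'   `iterations`, `rel_change`, `feas` (named violations at exit), `duals`,
#'   and `history` (data frame of per-check residuals).
#' @export
primal_dual_solve <- function(f_prox, terms, init, config = solver_config(),
                              init_duals = NULL, progress = NULL,
                              progress_floor = NULL, progress_scale = 1,
                              progress_patience = 0L) {
  stopifnot(is.function(f_prox), length(terms) >= 1)
  nb <- vapply(terms, function(tm) tm$op$norm_bound, numeric(1))
  stopifnot(all(is.finite(nb)), all(nb > 0))
  n_terms <- length(terms)
  tau <- config$step_scale / sqrt(sum(nb^2))
  # dual step budget allocated proportionally to each term's norm bound, so
  # stiff operators (the CT forward model) get correspondingly larger dual
  # steps; tau * sum_i sig_i * nb_i^2 = step_scale^2 < 1 holds either way
  sig <- config$step_scale / (tau * nb * sum(nb))

  x <- init
  x_prev_check <- x
  it_prev_check <- 0L
  prog_now <- NA_real_
  prog_prev <- NA_real_
  patience_hits <- 0L
  u <- if (!is.null(init_duals)) init_duals
       else lapply(terms, function(tm) vs_zero_like(op_apply(tm$op, x)))
  xbar <- x
  rel_change <- Inf
  feas_now <- rep(NA_real_, n_terms)
  names(feas_now) <- vapply(terms, `[[`, character(1), "name")
  hist_it <- integer(0); hist_rc <- numeric(0); hist_fmax <- numeric(0)
  hist_prog <- numeric(0)
  converged <- FALSE
  it <- 0L

  while (it < config$max_iters) {
    it <- it + 1L
    g <- NULL
    for (i in seq_len(n_terms)) {
      ai <- op_apply_adjoint(terms[[i]]$op, u[[i]])
      g <- if (is.null(g)) ai else vs_add(g, ai)
    }
    xnew <- f_prox(vs_sub(x, vs_scale(g, tau)), tau)
    xbar <- vs_sub(vs_scale(xnew, 2), x)
    rho <- config$relax
    for (i in seq_len(n_terms)) {
      ut <- vs_add(u[[i]], vs_scale(op_apply(terms[[i]]$op, xbar), sig[i]))
      unew <- vs_sub(ut, vs_scale(terms[[i]]$prox(vs_scale(ut, 1 / sig[i]), 1 / sig[i]), sig[i]))
      u[[i]] <- if (rho == 1) unew else vs_add(u[[i]], vs_scale(vs_sub(unew, u[[i]]), rho))
    }
    x <- if (rho == 1) xnew else vs_add(x, vs_scale(vs_sub(xnew, x), rho))

    if (it %% config$check_every == 0L || it == config$max_iters) {
      # stability is judged as the mean per-iteration relative drift over
      # the check window, which smooths the oscillation of primal-dual
      # iterates without penalizing long windows
      rel_change <- vs_norm(vs_sub(x, x_prev_check)) /
        max(vs_norm(x_prev_check), .Machine$double.eps) / (it - it_prev_check)
      if (!is.null(progress)) {
        prog_now <- progress(x)
        pdrift <- abs(prog_now - prog_prev) /
          max(progress_scale, .Machine$double.eps) / (it - it_prev_check)
        patience_hits <- if (!is.na(pdrift) && pdrift <= config$tol_primal)
          patience_hits + 1L else 0L
        prog_prev <- prog_now
      }
      x_prev_check <- x
      it_prev_check <- it
      for (i in seq_len(n_terms)) {
        if (is.null(terms[[i]]$feas)) {
          feas_now[i] <- 0
        } else {
          vi <- op_apply(terms[[i]]$op, x)  # eager: the application is real cost
          feas_now[i] <- terms[[i]]$feas(vi)
        }
      }
      fmax <- max(feas_now)
      hist_it <- c(hist_it, it); hist_rc <- c(hist_rc, rel_change)
      hist_fmax <- c(hist_fmax, fmax)
      hist_prog <- c(hist_prog, prog_now)
      if (config$verbose)
        message(sprintf("  iter %6d  rel %.3e  feas %.3e  prog %.3e",
                        it, rel_change, fmax, prog_now))
      at_floor <- !is.null(progress_floor) && !is.na(prog_now) &&
        prog_now <= progress_floor
      settled <- progress_patience > 0L && patience_hits >= progress_patience
      if (fmax <= config$tol_feas &&
          (rel_change <= config$tol_primal || at_floor || settled)) {
        converged <- TRUE
        break
      }
    }
  }

  list(x = x, converged = converged, iterations = it,
       rel_change = rel_change, feas = feas_now, duals = u,
       history = data.frame(iteration = hist_it, rel_change = hist_rc,
                            max_violation = hist_fmax,
                            progress = hist_prog))
}

## Relative distance-to-set helpers used to build `feas` closures; the same
## formulas back the user-facing membership checks so solver convergence and
## membership are judged on one scale.

.feas_l2_ball <- function(center, radius, scale = NULL) {
  # the set's scale: the larger of its radius and its distance from the
  # origin, so a tight ball around large-magnitude data is not judged on a
  # needlessly strict scale
  sc <- if (is.null(scale))
    max(radius, sqrt(sum(center^2)), .Machine$double.eps)
  else scale
  function(v) max(0, sqrt(sum((v - center)^2)) - radius) / sc
}

.feas_nonneg <- function() {
  function(v) {
    neg <- pmin(v, 0)
    sqrt(sum(neg^2)) / max(sqrt(sum(v^2)), .Machine$double.eps)
  }
}

.feas_l1_ball <- function(radius) {
  function(v) max(0, sum(abs(v)) - radius) / max(radius, .Machine$double.eps)
}
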