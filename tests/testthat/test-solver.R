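# Generic primal-dual solver: closed-form targets, fixed points, operator
# accounting, and the product-space distance machinery on a hand-built case.

test_that("solving a single ball constraint reproduces the closed-form projection", {
  ctr <- matrix(0.7, 6, 6)
  init <- matrix(3, 6, 6)
  tm <- pd_term(linear_op(identity, identity, 1, "id"),
                prox = function(v, tau) project_l2_ball(v, ctr, 0.5),
                feas = function(v) max(0, sqrt(sum((v - ctr)^2)) - 0.5) /
                  max(0.5, sqrt(sum(ctr^2))),
                name = "ball")
  # f = 0.5||. - init||^2 makes the solution the Euclidean projection
  sol <- primal_dual_solve(function(v, tau) (v + tau * init) / (1 + tau),
                           list(tm), init, solver_config(max_iters = 5000))
  expect_true(sol$converged)
  expect_equal(sol$x, project_l2_ball(init, ctr, 0.5), tolerance = 1e-3)
  # with f = 0 any feasible point is optimal; the solver must land in the set
  sol0 <- primal_dual_solve(function(v, tau) v, list(tm), init,
                            solver_config(max_iters = 5000))
  expect_true(sol0$converged)
  expect_lte(sqrt(sum((sol0$x - ctr)^2)), 0.5 * (1 + 1e-3))
})

test_that("a feasible init with f = 0 is an immediate fixed point", {
  ctr <- matrix(0, 5, 5)
  init <- matrix(0.01, 5, 5)  # well inside the radius-1 ball
  tm <- pd_term(linear_op(identity, identity, 1, "id"),
                prox = function(v, tau) project_l2_ball(v, ctr, 1),
                feas = function(v) max(0, sqrt(sum(v^2)) - 1),
                name = "ball")
  sol <- primal_dual_solve(function(v, tau) v, list(tm), init,
                           solver_config(max_iters = 2000))
  expect_true(sol$converged)
  expect_lte(sol$iterations, 200)
  expect_equal(sol$x, init, tolerance = 1e-4)
})

test_that("nonnegative least squares has its componentwise closed form", {
  a <- matrix(c(2, -1, 0.5, -0.25), 2, 2)
  # minimize 0.5||x - a||^2 s.t. x >= 0  ->  max(a, 0)
  tm <- pd_term(linear_op(identity, identity, 1, "id"),
                prox = function(v, tau) project_nonneg(v),
                feas = function(v) sqrt(sum(pmin(v, 0)^2)) /
                  max(sqrt(sum(v^2)), 1e-300),
                name = "nonneg")
  sol <- primal_dual_solve(function(v, tau) (v + tau * a) / (1 + tau),
                           list(tm), a * 0, solver_config(max_iters = 5000))
  expect_true(sol$converged)
  expect_equal(sol$x, pmax(a, 0), tolerance = 1e-4)
})

test_that("operator application counters are exact", {
  op <- linear_op(function(x) x * 2, function(u) u * 2, 2, "double")
  op_reset_counts(op)
  for (i in 1:7) op_apply(op, 1)
  for (i in 1:3) op_apply_adjoint(op, 1)
  expect_identical(op_counts(op), c(forward = 7L, adjoint = 3L))
  op_reset_counts(op)
  expect_identical(sum(op_counts(op)), 0L)
  # the solver's per-iteration pattern: one adjoint + one forward per term,
  # plus one forward per feasibility check and one at dual initialization
  tm <- pd_term(op, prox = function(v, tau) v * 0, feas = function(v) 0,
                name = "t")
  cfg <- solver_config(max_iters = 100, check_every = 10)
  sol <- primal_dual_solve(function(v, tau) v, list(tm), 1, cfg)
  it <- sol$iterations
  checks <- length(sol$history$iteration)
  expect_identical(op_counts(op),
                   c(forward = as.integer(1 + it + checks), adjoint = as.integer(it)))
})

test_that("product-space distance between two separated boxes equals the gap", {
  # two intervals on each of two pixels: S = [0, 1]^2, C = [3, 4] x [2, 5];
  # closest pair is (1, 1) vs (3, 2), distance sqrt(4 + 1)
  lo_s <- c(0, 0); hi_s <- c(1, 1)
  lo_c <- c(3, 2); hi_c <- c(4, 5)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  template <- list(xS = c(0, 0), xC = c(0, 0))
  lift <- function(block) {
    linear_op(function(z) z[[block]],
              function(u) { out <- list(xS = c(0, 0), xC = c(0, 0)); out[[block]] <- u; out },
              1, block)
  }
  tms <- list(
    pd_term(lift("xS"), prox = function(v, tau) clamp(v, lo_s, hi_s),
            feas = function(v) sqrt(sum((v - clamp(v, lo_s, hi_s))^2)), name = "S"),
    pd_term(lift("xC"), prox = function(v, tau) clamp(v, lo_c, hi_c),
            feas = function(v) sqrt(sum((v - clamp(v, lo_c, hi_c))^2)), name = "C"))
  couple <- function(z, tau) {
    d <- (z$xC - z$xS) * (tau / (1 + 2 * tau))
    list(xS = z$xS + d, xC = z$xC - d)
  }
  sol <- primal_dual_solve(couple, tms, list(xS = c(0.5, 0.5), xC = c(3.5, 3.5)),
                           solver_config(max_iters = 20000))
  expect_true(sol$converged)
  dist <- sqrt(sum((sol$x$xC - sol$x$xS)^2))
  # brute force over a fine grid of the two boxes
  gs <- expand.grid(a = seq(0, 1, 0.05), b = seq(0, 1, 0.05))
  gc <- expand.grid(a = seq(3, 4, 0.05), b = seq(2, 5, 0.05))
  dmin <- Inf
  for (i in seq_len(nrow(gs))) {
    d2 <- (gc$a - gs$a[i])^2 + (gc$b - gs$b[i])^2
    dmin <- min(dmin, min(d2))
  }
  expect_equal(dist, sqrt(dmin), tolerance = 1e-2)
  expect_equal(dist, sqrt(5), tolerance = 1e-2)
})
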