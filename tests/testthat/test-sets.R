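# Credible region and structure-absent set: the eta_alpha budget, the
# histogram parameter rule, membership checks, and the projection onto S.

test_that("eta_alpha follows the budget formula and is monotone in alpha", {
  # closed-form check on valid significance levels
  for (a in c(0.01, 0.1, 0.3)) {
    expect_equal(compute_eta_alpha(0, 1, a), 1 + sqrt(16 * log(3 / a)))
    expect_equal(compute_eta_alpha(5, 64, a),
                 5 + 64 + sqrt(16 * 64 * log(3 / a)))
  }
  e1 <- compute_eta_alpha(10, 256, 0.01)
  e2 <- compute_eta_alpha(10, 256, 0.05)
  e3 <- compute_eta_alpha(10, 256, 0.2)
  expect_gt(e1, e2); expect_gt(e2, e3)
  for (a in c(0.001, 0.05, 0.5))
    expect_gte(compute_eta_alpha(7, 99, a), 7 + 99)
  expect_error(compute_eta_alpha(1, 10, 1.5), "alpha")
  # verbatim reading keeps the linear-in-N slack
  expect_equal(compute_eta_alpha(0, 4, 0.3, reading = "verbatim"),
               4 + 64 * log(10))
})

test_that("histogram rule: degenerate annulus and percentile oracle", {
  img <- matrix(0.5, 32, 32)
  mask <- matrix(FALSE, 32, 32); mask[15:17, 15:17] <- TRUE
  s <- build_structure_set(img, mask, dilation_width = 3)
  expect_equal(s$mu_pix, 0.5)
  expect_equal(s$r_pix, 0)
  expect_equal(s$mu_grad, 0)
  expect_equal(s$r_grad, 0)
  expect_false(any(s$mask & s$neighborhood))
  # non-degenerate values against the brute-force percentile oracle
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11)
  img2 <- matrix(0, 32, 32)
  nb <- dilate_mask(mask, 3) & !mask
  idx <- which(nb)[seq_along(vals)]
  img2[idx] <- vals
  keep <- matrix(FALSE, 32, 32); keep[idx] <- TRUE; keep[mask] <- TRUE
  s2 <- build_structure_set(img2, mask, dilation_width = 3, within = keep)
  med <- oracle_percentile(vals, 0.5)
  expect_equal(s2$mu_pix, med)
  expect_equal(s2$r_pix, max(oracle_percentile(vals, 0.6) - med,
                             med - oracle_percentile(vals, 0.4)))
  expect_error(build_structure_set(img, mask, within = matrix(FALSE, 32, 32)),
               "neighborhood is empty")
})

test_that("the MAP estimate is a member of its own credible region", {
  run <- get_pe_run(100, 0.035, 1)
  m <- membership(run$map$x_dagger, run$cred, tol = 1e-4)
  expect_true(m$member)
  expect_named(m$violations, c("intensity", "data_ball", "psi_budget"))
})

test_that("membership flags the violated constraint", {
  run <- get_pe_run(100, 0.035, 1)
  bad <- run$map$x_dagger
  bad[3, 3] <- -1
  m <- membership(bad, run$cred, tol = 1e-4)
  expect_false(m$member)
  expect_gt(m$violations["intensity"], 1e-4)
})

test_that("single-pixel structure set projects by clamping (closed form)", {
  img <- matrix(0.2, 16, 16)
  img[8, 8] <- 2
  mask <- matrix(FALSE, 16, 16); mask[8, 8] <- TRUE
  s <- build_structure_set(img, mask, dilation_width = 2)
  s$r_grad <- Inf  # disable the gradient constraint
  p <- project_structure_set(img, s, quick_cfg())
  expect_true(attr(p, "converged"))
  target <- min(max(2, s$mu_pix - s$r_pix), s$mu_pix + s$r_pix)
  expect_equal(p[8, 8], max(target, 0), tolerance = 1e-3)
  expect_equal(p[mask == FALSE], img[mask == FALSE], tolerance = 1e-3)
})

test_that("projection onto S is idempotent, nonexpansive, and optimal vs sampling", {
  img <- seeded_image(8, 3)^2  # nonnegative-ish, rough
  mask <- matrix(FALSE, 8, 8); mask[4:5, 4:5] <- TRUE
  s <- build_structure_set(img, mask, dilation_width = 2)
  cfg <- quick_cfg()
  p <- project_structure_set(img, s, cfg)
  expect_true(attr(p, "converged"))
  expect_true(membership(p, s, tol = 1e-3)$member)
  p2 <- project_structure_set(p, s, cfg)
  expect_lte(sqrt(sum((p2 - p)^2)), 1e-2 * max(1, sqrt(sum(p^2))))
  # nonexpansive on probes
  img_b <- img + seeded_image(8, 9) * 0.1
  pb <- project_structure_set(img_b, s, cfg)
  expect_lte(sqrt(sum((p - pb)^2)), sqrt(sum((img - img_b)^2)) + 1e-3)
  # optimality: no sampled member of S is closer to img than p
  d_p <- sum((p - img)^2)
  for (zs in 1:1000) {
    z <- p
    pert <- withr::with_seed(zs, stats::rnorm(sum(mask), sd = 0.05))
    z[mask] <- pmax(s$mu_pix + project_l2_ball(pert, rep(0, length(pert)),
                                               s$r_pix * sqrt(s$n_s)), 0)
    if (membership(z, s, tol = 1e-6)$member)
      expect_gte(sum((z - img)^2), d_p - 1e-6)
  }
})

test_that("shrinking the radii never decreases the projection distance", {
  img <- abs(seeded_image(16, 4))
  mask <- matrix(FALSE, 16, 16); mask[7:9, 7:9] <- TRUE
  s <- build_structure_set(img, mask, dilation_width = 3)
  s$r_pix <- max(s$r_pix, 0.05); s$r_grad <- max(s$r_grad, 0.05)
  cfg <- quick_cfg()
  d_wide <- sqrt(sum((project_structure_set(img, s, cfg) - img)^2))
  s_narrow <- s
  s_narrow$r_pix <- s$r_pix / 4; s_narrow$r_grad <- s$r_grad / 4
  d_narrow <- sqrt(sum((project_structure_set(img, s_narrow, cfg) - img)^2))
  expect_gte(d_narrow, d_wide - 1e-3)
})
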