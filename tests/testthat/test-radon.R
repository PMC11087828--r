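# Parallel-beam forward model: geometry validation, linearity, the ray
# oracle, the exact adjoint, and the noise/epsilon machinery.

test_that("geometry construction validates its inputs", {
  g <- ct_geometry(10, 32, 32)
  expect_length(g$angles, 10)
  expect_true(all(g$angles >= 0 & g$angles < pi))
  expect_true(all(diff(g$angles) > 0))
  expect_error(ct_geometry(5, 16, 16, angles = c(0.5, 0.2, 0.9, 1.0, 1.1)),
               "increasing")
  expect_error(radon_forward(matrix(0, 8, 8), ct_geometry(4, 8, 16)),
               "geometry expects")
  expect_equal(paper_geometry(450, 32)$n_detectors, 450L)
})

test_that("forward projection is linear and zero maps to zero", {
  g <- tiny_geometry()
  a <- seeded_image(24, 1); b <- seeded_image(24, 2)
  expect_equal(radon_forward(matrix(0, 24, 24), g)$values,
               matrix(0, 12, 24))
  s_sum <- radon_forward(a + b, g)$values
  expect_equal(s_sum, radon_forward(a, g)$values + radon_forward(b, g)$values,
               tolerance = 1e-12)
  expect_equal(radon_forward(3 * a, g)$values, 3 * radon_forward(a, g)$values,
               tolerance = 1e-12)
})

test_that("projection of a centered disc matches the ray-traced oracle", {
  side <- 32
  ctr <- (side + 1) / 2
  rows <- matrix(seq_len(side), side, side); cols <- t(rows)
  r <- 8
  img <- matrix(0, side, side)
  img[(rows - ctr)^2 + (cols - ctr)^2 <= r^2] <- 1
  # central detector at angle 0: chord length of the full disc ~ 2r
  g0 <- ct_geometry(1, side, side)
  central <- radon_forward(img, g0)$values[1, side / 2]
  expect_equal(central, 2 * r, tolerance = 0.1 * r)
  # several angles/offsets against the independent ray-integration oracle
  g <- ct_geometry(4, side, side)
  sino <- radon_forward(img, g)$values
  for (a in 1:4) for (k in c(10, 16, 22)) {
    t_off <- k - (side + 1) / 2
    expect_equal(sino[a, k],
                 oracle_line_integral(img, g$angles[a], t_off),
                 tolerance = 0.6)  # discretization of both schemes
  }
})

test_that("adjoint identity holds to machine precision and Gram is positive", {
  g <- tiny_geometry()
  op <- radon_op(g)
  for (seed in 1:5) {
    x <- seeded_image(24, seed)
    u <- withr::with_seed(100 + seed, matrix(stats::rnorm(12 * 24), 12, 24))
    expect_lt(adjoint_discrepancy(op, x, u), 1e-6)
    s <- radon_forward(x, g)$values
    expect_gte(sum(s * s), 0)
  }
  z <- radon_adjoint(sinogram(matrix(0, 12, 24), g))
  expect_equal(z, matrix(0, 24, 24))
})

test_that("operator norm estimate is reproducible and dominates random probes", {
  g <- tiny_geometry()
  n1 <- radon_norm(g)
  n2 <- radon_norm(g)
  expect_equal(n1, n2)  # cached and seed-fixed
  for (seed in 1:20) {
    x <- seeded_image(24, seed)
    expect_lte(sqrt(sum(radon_forward(x, g)$values^2)),
               radon_op(g)$norm_bound * sqrt(sum(x^2)) * (1 + 1e-10))
  }
})

test_that("noise simulation honors sigma, seed, and the relative convention", {
  g <- ct_geometry(100, 120, 32)  # m_meas = 12000 >= 1e4
  img <- abs(seeded_image(32, 3))
  clean <- radon_forward(img, g)$values
  y0 <- simulate_measurements(img, g, 0, seed = 1)
  expect_identical(y0$values, clean)
  sg <- 0.3
  y1 <- simulate_measurements(img, g, sg, seed = 1)
  emp_sd <- stats::sd(y1$values - clean)
  expect_lt(abs(emp_sd - sg) / sg, 0.05)
  y1b <- simulate_measurements(img, g, sg, seed = 1)
  expect_identical(y1$values, y1b$values)
  y2 <- simulate_measurements(img, g, sg, seed = 2)
  expect_false(identical(y1$values, y2$values))
  yr <- simulate_measurements(img, g, 0.1, seed = 1, relative = TRUE)
  expect_equal(attr(yr, "sigma_abs"), 0.1 * max(abs(clean)))
})

test_that("epsilon bound matches the chi-square quantile and concentrates", {
  expect_equal(epsilon_bound(0, 100, 0.9), 0)
  # m = 1, two-sided 95.45% quantile of |N(0,1)| is ~2
  expect_equal(epsilon_bound(1.5, 1, 0.9545), 1.5 * 2, tolerance = 1e-3)
  # chi-square concentration: eps / (sigma sqrt(m)) -> 1
  expect_equal(epsilon_bound(2, 1e6, 0.99) / (2 * sqrt(1e6)), 1,
               tolerance = 5e-3)
  expect_error(epsilon_bound(1, 10, 1.2))
  # coverage: ||w||_2 <= eps in about 99% of seeded draws
  m <- 400
  eps <- epsilon_bound(1, m, 0.99)
  hits <- vapply(1:1000, function(s) {
    w <- withr::with_seed(s, stats::rnorm(m))
    sqrt(sum(w^2)) <= eps
  }, logical(1))
  expect_gte(mean(hits), 0.975)  # binomial band around 0.99
})
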