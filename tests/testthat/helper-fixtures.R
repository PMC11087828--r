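# Shared fixtures and independent oracles for the test suite. Expensive
# pipeline runs are cached in .fix so several test files can reuse them
# within one run.

.fix <- new.env(parent = emptyenv())

# iteration budget for end-to-end suite runs (documented desk scale);
# distance solves that exhaust it are flagged and carry upper-bound
# estimates, which the statistical suites account for
quick_cfg <- function(max_iters = 8000, ...) {
  solver_config(max_iters = max_iters, ...)
}

# small reusable geometry + random probes
tiny_geometry <- function(ma = 12, d = 24, side = 24) ct_geometry(ma, d, side)

seeded_image <- function(side, seed = 1) {
  withr::with_seed(seed, matrix(stats::rnorm(side * side), side, side))
}

# cached end-to-end run on a structure-present scenario
get_pe_run <- function(ma, sigma, seed, side = 64, ...) {
  key <- paste("pe", ma, sigma, seed, side, sep = "_")
  if (is.null(.fix[[key]])) {
    sc <- make_pe_scenario(ma, sigma, seed, side = side)
    .fix[[key]] <- run_test(sc, map_config = quick_cfg(), ...)
  }
  .fix[[key]]
}

# cached artifact scenario + its run
get_artifact_run <- function(seed, side = 64) {
  key <- paste("art", seed, side, sep = "_")
  if (is.null(.fix[[key]])) {
    sc <- make_artifact_scenario(seed, side = side, config = quick_cfg())
    .fix[[key]] <- run_test(sc, map_config = quick_cfg())
  }
  .fix[[key]]
}

## ---- independent oracles -------------------------------------------------

# brute-force ray-traced line integral through a pixel image: sample the ray
# densely and sum bilinearly interpolated values (independent of the
# pixel-driven operator under test)
oracle_line_integral <- function(image, theta, t_offset, step = 0.01) {
  side <- nrow(image)
  half <- (side + 1) / 2
  # ray: points p(s) = t * (cos, sin) + s * (-sin, cos) in (col, row) coords
  smax <- side  # long enough to cross the image
  svals <- seq(-smax, smax, by = step)
  cols <- t_offset * cos(theta) - svals * sin(theta) + half
  rows <- t_offset * sin(theta) + svals * cos(theta) + half
  ok <- rows >= 1 & rows <= side & cols >= 1 & cols <= side
  rows <- rows[ok]; cols <- cols[ok]
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  r1 <- pmin(r0 + 1, side); c1 <- pmin(c0 + 1, side)
  v <- image[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
       image[cbind(r1, c0)] * fr * (1 - fc) +
       image[cbind(r0, c1)] * (1 - fr) * fc +
       image[cbind(r1, c1)] * fr * fc
  sum(v) * step
}

# exhaustive KKT breakpoint scan for the l1-ball projection (short vectors)
oracle_l1_projection <- function(x, radius) {
  if (sum(abs(x)) <= radius) return(x)
  if (radius == 0) return(x * 0)
  a <- sort(abs(x), decreasing = TRUE)
  # candidate thresholds: scan all breakpoints where the support changes
  best <- NULL
  for (k in seq_along(a)) {
    theta <- (sum(a[1:k]) - radius) / k
    if (theta >= 0 &&
        theta < a[k] + 1e-15 &&
        (k == length(a) || theta >= a[k + 1] - 1e-12)) {
      best <- theta
      break
    }
  }
  stopifnot(!is.null(best))
  sign(x) * pmax(abs(x) - best, 0)
}

# percentile rule oracle: linear interpolation between order statistics
# computed from first principles (type-7 convention)
oracle_percentile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}
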