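# Linear, cubic-spline and CIC interpolation against independent oracles.

test_that("linear interpolation matches the two-point formula", {
  s <- sampled_series(c(0, 0.04), c(0, 1))
  expect_equal(linear_interpolate(s, 0.02), 0.5)
  expect_equal(linear_interpolate(s, c(0, 0.04)), c(0, 1)) # knot identity

  set.seed(101)
  for (rep in 1:100) {
    n <- sample(3:30, 1L)
    ts <- sort(runif(n, 0, 10))
    ts <- ts + seq_len(n) * 1e-6 # ensure distinct
    ys <- rnorm(n)
    ser <- sampled_series(ts, ys)
    q <- runif(50, min(ts), max(ts))
    got <- linear_interpolate(ser, q)
    # direct per-interval evaluation of the formula
    want <- vapply(q, function(t) {
      i <- max(which(ts <= t))
      if (i == n) return(ys[n])
      ys[i] + (ys[i + 1L] - ys[i]) / (ts[i + 1L] - ts[i]) * (t - ts[i])
    }, numeric(1))
    expect_lt(max(abs(got - want)), 1e-12)
    # cross-check against stats::approx with clamped rule
    ap <- approx(ts, ys, xout = q, rule = 2)$y
    expect_lt(max(abs(got - ap)), 1e-12)
  }
})

test_that("linear interpolation clamps outside the span and validates input", {
  s <- sampled_series(c(0, 1, 2), c(5, 7, -1))
  expect_equal(linear_interpolate(s, c(-3, 10)), c(5, -1))
  expect_error(linear_interpolate(sampled_series(c(1, 1), c(2, 4)), 1), "two distinct")
  expect_error(linear_interpolate(s, c(0.5, NA)), "finite")
})

test_that("cubic spline on collinear data is the straight line", {
  s <- sampled_series(c(0, 0.5, 1.2, 3), 2 + 4 * c(0, 0.5, 1.2, 3))
  fit <- fit_cubic_spline(s)
  expect_equal(unname(fit$coefficients[, "a"]), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[, "b"]), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[, "c"]), rep(4, 3), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[, "d"]), s$values[1:3], tolerance = 1e-12)
  expect_equal(evaluate_spline(fit, 0.85), 2 + 4 * 0.85, tolerance = 1e-10)
})

test_that("cubic spline agrees with the dense full-system solve", {
  set.seed(202)
  for (rep in 1:5) {
    ts <- sort(runif(20, 0, 5)) + seq_len(20) * 1e-5
    ys <- rnorm(20)
    fit <- fit_cubic_spline(sampled_series(ts, ys))
    want <- spline_full_system(ts, ys)
    scale <- pmax(abs(want), 1)
    expect_lt(max(abs(fit$coefficients - want) / scale), 1e-8)
    # and with the reference natural-spline evaluator
    q <- runif(100, min(ts), max(ts))
    ref <- splinefun(ts, ys, method = "natural")(q)
    expect_lt(max(abs(evaluate_spline(fit, q) - ref)), 1e-9)
  }
})

test_that("cubic spline is continuous in value and first two derivatives", {
  set.seed(203)
  ts <- cumsum(runif(15, 0.1, 0.5))
  ys <- rnorm(15)
  fit <- fit_cubic_spline(sampled_series(ts, ys))
  h <- diff(ts)
  co <- fit$coefficients
  # interval i evaluated at its right knot reproduces the knot value
  right <- ((co[, "a"] * h + co[, "b"]) * h + co[, "c"]) * h + co[, "d"]
  expect_equal(unname(right), ys[-1L], tolerance = 1e-9)
  # derivative jumps at interior knots, from the returned polynomial pieces:
  # left piece end derivatives must match the right piece start derivatives
  nseg <- length(h)
  d1_left <- 3 * co[-nseg, "a"] * h[-nseg]^2 + 2 * co[-nseg, "b"] * h[-nseg] + co[-nseg, "c"]
  d1_right <- co[-1L, "c"]
  d2_left <- 6 * co[-nseg, "a"] * h[-nseg] + 2 * co[-nseg, "b"]
  d2_right <- 2 * co[-1L, "b"]
  scale1 <- pmax(abs(d1_left), 1)
  scale2 <- pmax(abs(d2_left), 1)
  expect_lt(max(abs(d1_left - d1_right) / scale1), 1e-6)
  expect_lt(max(abs(d2_left - d2_right) / scale2), 1e-6)
  # finite-difference sanity check of the first-derivative match across knots
  eps <- 1e-6
  for (i in c(3L, 8L, 13L)) {
    one_sided_l <- (evaluate_spline(fit, ts[i]) - evaluate_spline(fit, ts[i] - eps)) / eps
    one_sided_r <- (evaluate_spline(fit, ts[i] + eps) - evaluate_spline(fit, ts[i])) / eps
    # truncation error of one-sided differences is O(eps * |x''|)
    expect_lt(abs(one_sided_l - one_sided_r), 1e-3 * max(1, abs(one_sided_l)))
  }
  # natural boundary: zero curvature at both ends
  expect_lt(abs(2 * co[1L, "b"]), 1e-9)
  expect_lt(abs(6 * co[nseg, "a"] * h[nseg] + 2 * co[nseg, "b"]), 1e-9)
})

test_that("spline handles degenerate series as documented", {
  # duplicates collapsed by value averaging
  s <- sampled_series(c(0, 1, 1, 2, 3), c(0, 2, 4, 1, 5))
  fit <- fit_cubic_spline(s)
  expect_identical(fit$knots, c(0, 1, 2, 3))
  expect_equal(fit$values[2L], 3) # mean of 2 and 4
  # fewer than 3 distinct knots: linear fallback with warning
  expect_warning(f2 <- fit_cubic_spline(sampled_series(c(0, 2), c(1, 5))), "linear")
  expect_equal(evaluate_spline(f2, 1), 3)
  expect_error(fit_cubic_spline(sampled_series(1, 2)), "two distinct")
})

test_that("evaluate_spline clamps outside the knot span", {
  ts <- c(0, 1, 2, 3)
  ys <- c(1, -2, 0, 4)
  fit <- fit_cubic_spline(sampled_series(ts, ys))
  expect_equal(evaluate_spline(fit, c(-5, 99)), c(1, 4))
  expect_equal(evaluate_spline(fit, ts), ys, tolerance = 1e-9)
})

test_that("all interpolators are linear operators in the input values", {
  set.seed(301)
  grid <- std_grid(200)
  ts <- sort(runif(180, 0, 200 / 25))
  ts[1] <- 0; ts[180] <- 199 / 25
  for (m in c("linear", "cubic", "cic")) {
    x <- rnorm(180); y <- rnorm(180)
    al <- 1.7; be <- -0.6
    mk <- function(v) sampled_series(ts, v, 25)
    lhs <- reconstruct(mk(al * x + be * y), grid, m)
    rhs <- al * reconstruct(mk(x), grid, m) + be * reconstruct(mk(y), grid, m)
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("CIC cascade equals an N-fold boxcar: impulse and random input", {
  L <- 20L; N <- 4L
  # impulse response = N-fold self-convolution of a length-L boxcar
  imp <- c(1, numeric(120))
  want <- 1
  for (i in seq_len(N)) want <- convolve(want, rev(rep(1, L)), type = "open")
  got <- cic_filter_cascade(imp, L, N)
  # response support is N(L-1)+1 = 77 samples; zero beyond
  expect_length(want, N * (L - 1L) + 1L)
  expect_equal(got[seq_along(want)], want, tolerance = 1e-9)
  expect_lt(max(abs(got[-seq_along(want)])), 1e-9)

  # random length-750 input vs. repeated moving-average (stats::filter)
  set.seed(401)
  x <- rnorm(750)
  ma <- x
  for (i in seq_len(N)) ma <- as.numeric(stats::filter(ma, rep(1, L), sides = 1))
  got2 <- cic_filter_cascade(x, L, N)
  valid <- !is.na(ma)
  expect_lt(max(abs(got2[valid] - ma[valid])), 1e-9)
})

test_that("CIC interpolation preserves DC and tracks the analytic droop", {
  grid <- std_grid()
  const <- sampled_series(grid_times(grid), rep(4.2, 750), 25)
  out <- cic_interpolate(const, grid)
  expect_lt(max(abs(out - 4.2)) / 4.2, 1e-6)

  # unit-power 1.2 Hz tone on a regular 25 Hz grid: reconstruction error is
  # dominated by the passband droop (|sin(pi f L / f_hi) / (L sin(pi f / f_hi))|)^N
  dense <- generate_sinusoid(30, freq_hz = 1.2, phase_rad = 0.7)
  ref <- sample_regular(dense, grid)
  rec <- cic_interpolate(ref, grid)
  measured <- rmse(rec, ref$values)
  cfg <- cic_config()
  f_hi <- 25 * cfg$R; L <- cfg$R * cfg$M
  droop <- (sin(pi * 1.2 * L / f_hi) / (L * sin(pi * 1.2 / f_hi)))^cfg$N
  predicted <- (1 - droop) * 1 # unit-power signal
  expect_lt(measured, 1.5 * predicted)
  expect_gt(measured, 0.5 * predicted)
})

test_that("CIC interpolation fills unsupported grid points with a warning", {
  grid <- std_grid(100)
  sparse <- sampled_series(c(0, 0.04), c(1, 1), 25)
  expect_warning(out <- cic_interpolate(sparse, grid, cic_config()), "support")
  expect_length(out, 100L)
  expect_true(all(is.finite(out)))
})

test_that("reconstruct dispatches and is exact at uncorrupted grid points", {
  dense <- generate_sinusoid(30, seed = 51)
  grid <- std_grid()
  ref <- sample_regular(dense, grid)
  expect_equal(reconstruct(ref, grid, "linear"), ref$values, tolerance = 1e-9)
  expect_equal(reconstruct(ref, grid, "cubic"), ref$values, tolerance = 1e-9)
  expect_error(reconstruct(ref, grid, "sinc"), "arg")

  lossy <- apply_sample_loss(ref, loss_spec(10, seed = 1))
  for (m in c("linear", "cubic", "cic")) {
    vals <- reconstruct(lossy, grid, m)
    expect_length(vals, 750L)
    expect_true(all(is.finite(vals)))
  }
})

test_that("cubic correction beats no processing on almost every lossy draw", {
  grid <- std_grid()
  wins <- 0L
  n_trials <- 500L
  for (i in seq_len(n_trials)) {
    dense <- generate_sinusoid(30, seed = derive_seed(77, i, 1L))
    ref <- sample_regular(dense, grid)
    k <- derive_seed(77, i, 2L) %% 50L + 1L
    lossy <- apply_sample_loss(ref, loss_spec(k, seed = derive_seed(77, i, 3L)))
    err_none <- rmse(lossy$values, ref$values[seq_along(lossy$values)])
    err_cubic <- rmse(reconstruct(lossy, grid, "cubic"), ref$values)
    if (err_cubic < err_none) wins <- wins + 1L
  }
  expect_gte(wins / n_trials, 0.99)
})
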