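# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: dense linear-system solves, explicit loops,
# and closed-form identities.

# Natural cubic spline solved as the full dense 4(n-1) x 4(n-1) linear
# system: interpolation at both interval ends, C1/C2 continuity at interior
# knots, zero second derivative at the boundary knots.
spline_full_system <- function(s, y) {
  n <- length(s)
  h <- diff(s)
  m <- 4L * (n - 1L)
  A <- matrix(0, m, m)
  b <- numeric(m)
  col <- function(i, j) (i - 1L) * 4L + j # unknowns (a_i, b_i, c_i, d_i)
  r <- 0L
  for (i in seq_len(n - 1L)) {
    r <- r + 1L; A[r, col(i, 4L)] <- 1; b[r] <- y[i]
    r <- r + 1L
    A[r, col(i, 1L):col(i, 4L)] <- c(h[i]^3, h[i]^2, h[i], 1)
    b[r] <- y[i + 1L]
  }
  for (i in seq_len(n - 2L)) {
    r <- r + 1L
    A[r, col(i, 1L):col(i, 3L)] <- c(3 * h[i]^2, 2 * h[i], 1)
    A[r, col(i + 1L, 3L)] <- -1
    r <- r + 1L
    A[r, col(i, 1L)] <- 6 * h[i]
    A[r, col(i, 2L)] <- 2
    A[r, col(i + 1L, 2L)] <- -2
  }
  r <- r + 1L; A[r, col(1L, 2L)] <- 2
  r <- r + 1L; A[r, col(n - 1L, 1L)] <- 6 * h[n - 1L]; A[r, col(n - 1L, 2L)] <- 2
  coef <- matrix(solve(A, b), ncol = 4L, byrow = TRUE)
  colnames(coef) <- c("a", "b", "c", "d")
  coef
}

# Dominant band-limited frequency by an explicit DFT correlation loop.
band_scan_peak <- function(x, rate, f_lo, f_hi) {
  n <- length(x)
  xc <- x - mean(x)
  idx <- 0:(n - 1L)
  ks <- 0:floor(n / 2)
  freqs <- ks * rate / n
  sel <- which(freqs >= f_lo & freqs <= f_hi)
  mags <- vapply(sel, function(j) {
    k <- ks[j]
    re <- sum(xc * cos(2 * pi * k * idx / n))
    im <- sum(xc * sin(2 * pi * k * idx / n))
    sqrt(re^2 + im^2)
  }, numeric(1))
  freqs[sel][which.max(mags)]
}

# Standard deviation of a N(0, sigma^2) draw clipped (not resampled) to
# [-c, c], from the closed-form second moment.
clipped_normal_sd <- function(sigma, c) {
  a <- c / sigma
  m2 <- sigma^2 * ((2 * stats::pnorm(a) - 1) - 2 * a * stats::dnorm(a)) +
    c^2 * 2 * (1 - stats::pnorm(a))
  sqrt(m2)
}

# A regular 25 Hz / 750-sample analysis window.
std_grid <- function(count = 750, rate = 25) uniform_grid(0, rate, count)
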