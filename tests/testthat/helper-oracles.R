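# Independent oracles used across the threshold tests. These deliberately
# re-derive each quantity from its definition (loops, explicit class sums)
# rather than sharing code with the package implementation.

# Exhaustive between-class variance scan: try every cut point, compute class
# weights and means explicitly. Returns the variance at each cut (index t+1
# holds cut level t); cuts with an empty class get -Inf.
otsu_variance_scan <- function(counts) {
  g <- 0:255
  total <- sum(counts)
  v <- rep(-Inf, 255)
  for (t in 0:254) {
    lo <- counts[1:(t + 1)]
    hi <- counts[(t + 2):256]
    w0 <- sum(lo) / total
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(g[1:(t + 1)] * lo) / sum(lo)
    mu1 <- sum(g[(t + 2):256] * hi) / sum(hi)
    v[t + 1] <- w0 * w1 * (mu0 - mu1)^2
  }
  v
}

# Lowest level attaining the scan maximum (ties resolved to the lowest level;
# the tolerance absorbs floating-point noise between algebraically equivalent
# formulations).
otsu_oracle <- function(counts) {
  v <- otsu_variance_scan(counts)
  vmax <- max(v)
  which(v >= vmax - 1e-9 * max(1, abs(vmax)))[1] - 1L
}

# Clean-room Tsai moment-preserving threshold: gray-level moments m1..m3 of
# the normalized histogram, the two representative levels z0 < z1 solving the
# moment-matching quadratic, the preserved background fraction p0, and the
# p0-tile of the histogram.
tsai_oracle <- function(counts) {
  p <- counts / sum(counts)
  z <- 0:255
  m1 <- sum(z * p); m2 <- sum(z^2 * p); m3 <- sum(z^3 * p)
  cd <- m2 - m1 * m1
  if (cd <= 0) return(which.max(counts) - 1L)
  c0 <- (m1 * m3 - m2 * m2) / cd
  c1 <- (m2 * m1 - m3) / cd
  disc <- c1 * c1 - 4 * c0
  if (disc < 0) return(which.max(counts) - 1L)
  z0 <- (-c1 - sqrt(disc)) / 2
  z1 <- (-c1 + sqrt(disc)) / 2
  if (z1 <= z0) return(which.max(counts) - 1L)
  p0 <- (z1 - m1) / (z1 - z0)
  cum <- 0
  for (t in 0:255) {
    cum <- cum + p[t + 1]
    if (cum >= p0) return(t)
  }
  255L
}

# One step of the Li & Tam minimum cross-entropy update for a given integer
# threshold: background/foreground means under the split, then the
# log-mean-ratio formula.
li_update_oracle <- function(counts, t) {
  g <- 0:255
  back <- g <= t
  sb <- sum(counts[back]); sf <- sum(counts[!back])
  mu_b <- if (sb > 0) sum(g[back] * counts[back]) / sb else 1e-10
  mu_f <- if (sf > 0) sum(g[!back] * counts[!back]) / sf else 255
  mu_b <- max(mu_b, 1e-10)
  mu_f <- max(mu_f, 1e-10)
  (mu_b - mu_f) / (log(mu_b) - log(mu_f))
}

# Brute-force minimum cross-entropy scan (Li's criterion evaluated at every
# cut point).
li_xent_scan <- function(counts) {
  g <- 0:255
  best <- Inf; best_t <- 0L
  for (t in 0:254) {
    back <- g <= t
    sb <- sum(counts[back]); sf <- sum(counts[!back])
    if (sb == 0 || sf == 0) next
    mu_b <- sum(g[back] * counts[back]) / sb
    mu_f <- sum(g[!back] * counts[!back]) / sf
    if (mu_b <= 0) mu_b <- 1e-10
    xent <- -(sb * mu_b * log(mu_b) + sf * mu_f * log(mu_f))
    if (xent < best - 1e-12) { best <- xent; best_t <- t }
  }
  best_t
}

# Random histogram generator for property-style sweeps: mixtures of discrete
# Gaussians, occasional spikes and uniform floors.
random_histogram <- function() {
  n_modes <- sample(1:3, 1)
  h <- rep(0, 256)
  for (i in seq_len(n_modes)) {
    mu <- runif(1, 0, 255)
    sdv <- runif(1, 2, 40)
    h <- h + round(1000 * exp(-((0:255) - mu)^2 / (2 * sdv^2)))
  }
  if (runif(1) < 0.3) h <- h + sample(0:3, 256, replace = TRUE)
  if (runif(1) < 0.3) h[sample(1:256, 3)] <- h[sample(1:256, 3)] + 5000
  if (sum(h) == 0) h[129] <- 1
  h
}

gaussian_mixture_hist <- function(mean1 = 60, mean2 = 190, sd = 10, n = 20000) {
  x1 <- round(1000 * exp(-((0:255) - mean1)^2 / (2 * sd^2)))
  x2 <- round(1000 * exp(-((0:255) - mean2)^2 / (2 * sd^2)))
  x1 + x2
}

# Li's cross-entropy criterion value at an integer cut point.
li_xent_value <- function(counts, t) {
  g <- 0:255
  back <- g <= t
  sb <- sum(counts[back]); sf <- sum(counts[!back])
  mu_b <- if (sb > 0) sum(g[back] * counts[back]) / sb else 1e-10
  mu_f <- if (sf > 0) sum(g[!back] * counts[!back]) / sf else 1e-10
  if (mu_b <= 0) mu_b <- 1e-10
  -(sb * mu_b * log(mu_b) + sf * mu_f * log(mu_f))
}
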