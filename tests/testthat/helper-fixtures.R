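# Fixtures built in code; all randomness seeded locally.

# A recording with known content: sinusoidal channels, fs 100.
make_test_recording <- function(n = 500, fs = 100, subject = "T01") {
  t <- (seq_len(n) - 1) / fs
  ch <- list(
    ACC_X = 0.2 * sin(2 * pi * 1.1 * t),
    ACC_Y = 0.3 * abs(sin(2 * pi * 0.9 * t)) + 1,
    ACC_Z = 0.1 * cos(2 * pi * 0.9 * t),
    GYRO_X = 30 * sin(2 * pi * 0.8 * t + 0.3),
    GYRO_Y = 50 * sin(2 * pi * 0.9 * t),
    GYRO_Z = 40 * cos(2 * pi * 0.9 * t + 1)
  )
  imu_recording(ch, fs, subject_id = subject)
}

# Dataset with one perfectly separating attribute among noise attributes.
# Two rows (walks) per subject so grouped operations are exercised.
make_planted_dataset <- function(n_subj = 24, p_noise = 15, seed = 101) {
  set.seed(seed)
  n <- 2 * n_subj
  y_subj <- rep(0:1, length.out = n_subj)
  y <- rep(y_subj, each = 2)
  X <- matrix(rnorm(n * (p_noise + 1)), n)
  colnames(X) <- c(sprintf("noise%02d", seq_len(p_noise)), "planted")
  X[, "planted"] <- y * 6 + rnorm(n, 0, 0.3)
  labeled_dataset(X, y, subject_ids = rep(sprintf("P%02d", seq_len(n_subj)), each = 2))
}

# XOR construction: neither attribute separates alone, both together do.
# Values are exactly binary so the only available tree splits are the true
# class boundaries, and quadrant sizes are unequal so single-feature splits
# have positive gini gain and greedy trees can descend to the interaction.
make_xor_dataset <- function() {
  sizes <- c(12L, 10L, 10L, 8L)              # (a,b) = (0,0),(0,1),(1,0),(1,1)
  ab <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  a <- rep(ab[, 1], sizes)
  b <- rep(ab[, 2], sizes)
  y <- as.integer(xor(a > 0.5, b > 0.5))
  labeled_dataset(cbind(A = a, B = b), y)
}

# Linearly separated toy data, margin much larger than noise.
make_separable_dataset <- function(n_per_class = 20, seed = 5) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(0:1, each = n_per_class)
  X <- cbind(a = y * 4 + rnorm(n, 0, 0.3), b = rnorm(n))
  labeled_dataset(X, y)
}

# --- independent oracles -----------------------------------------------------

# Poincare via literal geometry: signed distances of (x_i, x_{i+lag}) to the
# identity line and along it.
oracle_poincare <- function(x, lag = 1L) {
  n <- length(x)
  a <- x[seq_len(n - lag)]
  b <- x[seq_len(n - lag) + lag]
  perp <- (b - a) / sqrt(2)
  along <- (a + b) / sqrt(2)
  popsd <- function(v) sqrt(mean((v - mean(v))^2))
  list(sd1 = popsd(perp), sd2 = popsd(along))
}

# Spectral moments via an explicit O(n^2) DFT and literal moment sums.
oracle_spectral <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  k <- seq_len(n %/% 2)
  W <- exp(-2i * pi * outer(k, seq_len(n) - 1) / n)
  amp2 <- Mod(W %*% x)^2 / n^2
  amp2[k < n / 2] <- 2 * amp2[k < n / 2]
  freq <- k * fs / n
  p <- as.vector(amp2 / sum(amp2))
  mu <- sum(freq * p)
  m2 <- sum((freq - mu)^2 * p)
  list(
    dominant_freq = freq[which.max(amp2)],
    centroid = mu, bandwidth = sqrt(m2),
    skew = if (m2 > 0) sum((freq - mu)^3 * p) / m2^1.5 else 0,
    kurt = if (m2 > 0) sum((freq - mu)^4 * p) / m2^2 else NaN,
    entropy = -sum(p[p > 0] * log(p[p > 0])),
    total_power = sum(amp2)
  )
}

# Literal scans for crossings and strict local maxima.
oracle_crossings <- function(x, fs) {
  x <- x - mean(x)
  s <- numeric(length(x))
  cur <- 0
  for (i in seq_along(x)) {
    if (x[i] != 0) cur <- sign(x[i])
    s[i] <- cur
  }
  if (any(s == 0)) s[s == 0] <- s[s != 0][1]
  at <- integer(0)
  for (i in seq_len(length(x) - 1)) if (s[i] * s[i + 1] < 0) at <- c(at, i + 1L)
  ints <- diff(at) / fs
  popsd <- function(v) sqrt(mean((v - mean(v))^2))
  list(n = length(at),
       mean = if (length(ints)) mean(ints) else 0,
       sd = if (length(ints)) popsd(ints) else 0)
}

oracle_peaks <- function(x, fs) {
  n <- length(x)
  at <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[j]) j <- j + 1
      if (j < n && x[j + 1] < x[j]) at <- c(at, i)
    }
  }
  ints <- diff(at) / fs
  popsd <- function(v) sqrt(mean((v - mean(v))^2))
  list(n = length(at),
       mean = if (length(ints)) mean(ints) else 0,
       sd = if (length(ints)) popsd(ints) else 0)
}
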