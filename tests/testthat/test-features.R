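test_that("Poincare descriptors match hand-computed cases and the geometric oracle", {
  p <- poincare_descriptors(c(5, 5, 5, 5))
  expect_equal(p$sd1, 0)
  expect_equal(p$sd2, 0)

  p <- poincare_descriptors(c(1, -1, 1, -1, 1))
  expect_equal(p$sd1, sqrt(2))
  expect_equal(p$sd2, 0)

  p <- poincare_descriptors(c(1, 2, 3, 4))
  expect_equal(p$sd1, 0)
  expect_equal(p$sd2, sqrt(4 / 3))

  expect_error(poincare_descriptors(c(1, 2), lag = 1),
               class = "hemigait_validation_error")

  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(sample(10:200, 1))
    lag <- sample(1:3, 1)
    got <- poincare_descriptors(x, lag)
    want <- oracle_poincare(x, lag)
    expect_equal(got$sd1, want$sd1, tolerance = 1e-12)
    expect_equal(got$sd2, want$sd2, tolerance = 1e-12)
  }
})

test_that("Poincare identity, shift invariance, and scaling hold", {
  set.seed(22)
  for (i in 1:20) {
    x <- cumsum(rnorm(150))
    p <- poincare_descriptors(x)
    n <- length(x)
    a <- x[-n]; b <- x[-1]
    popvar <- function(v) mean((v - mean(v))^2)
    expect_equal(p$sd1^2 + p$sd2^2, popvar(a) + popvar(b), tolerance = 1e-10)
    shifted <- poincare_descriptors(x + 17.3)
    expect_equal(shifted$sd1, p$sd1, tolerance = 1e-10)
    scaled <- poincare_descriptors(2.5 * x)
    expect_equal(scaled$sd1, 2.5 * p$sd1, tolerance = 1e-10)
  }
})

test_that("spectral moments match closed forms for constructed spectra", {
  t <- (0:199) / 100
  s <- spectral_moments(sin(2 * pi * 5 * t), 100)
  expect_equal(s$dominant_freq, 5)
  expect_equal(s$centroid, 5, tolerance = 1e-9)
  expect_equal(s$bandwidth, 0, tolerance = 1e-6)
  expect_equal(s$skew, 0)

  # equal mass at two bins: symmetric two-point pmf has kurtosis exactly 1
  s2 <- spectral_moments(sin(2 * pi * 5 * t) + sin(2 * pi * 15 * t), 100)
  expect_equal(s2$centroid, 10, tolerance = 1e-9)
  expect_equal(s2$skew, 0, tolerance = 1e-9)
  expect_equal(s2$kurt, 1, tolerance = 1e-9)

  # discrete uniform over K bins: kurt = 3 - 6(K^2+1) / (5(K^2-1))
  K <- 101
  m <- spectral_moments_from_pmf(seq_len(K), rep(1 / K, K))
  expect_equal(m$kurt, 3 - 6 * (K^2 + 1) / (5 * (K^2 - 1)), tolerance = 1e-12)
  expect_equal(m$entropy, log(K), tolerance = 1e-12)

  expect_error(spectral_moments(rep(1, 100), 100),
               class = "hemigait_degenerate_error")
  expect_error(spectral_moments(rnorm(5), 100),
               class = "hemigait_validation_error")
})

test_that("spectral moments agree with a brute-force DFT oracle", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(c(32, 50, 64, 100), 1)
    x <- rnorm(n) + sin(2 * pi * 3 * (1:n) / n)
    got <- spectral_moments(x, 50)
    want <- oracle_spectral(x, 50)
    expect_equal(got$centroid, want$centroid, tolerance = 1e-9)
    expect_equal(got$bandwidth, want$bandwidth, tolerance = 1e-9)
    expect_equal(got$skew, want$skew, tolerance = 1e-9)
    expect_equal(got$kurt, want$kurt, tolerance = 1e-9)
    expect_equal(got$entropy, want$entropy, tolerance = 1e-9)
    expect_equal(got$total_power, want$total_power, tolerance = 1e-9)
    # Parseval: one-sided power (DC removed) recovers the variance
    expect_equal(got$total_power, mean((x - mean(x))^2), tolerance = 1e-6)
  }
})

test_that("crossing and peak statistics match enumeration and literal-scan oracles", {
  cs <- crossing_stats(c(1, -1, 1, -1), fs = 1)
  expect_equal(cs$n_crossings, 3)
  expect_equal(cs$mean_interval_s, 1)
  expect_equal(cs$sd_interval_s, 0)

  cs <- crossing_stats(rep(2, 10), fs = 1)
  expect_equal(cs$n_crossings, 0)
  expect_equal(cs$mean_interval_s, 0)

  cs <- crossing_stats(c(1, 2, 3, 4), fs = 1)   # centered ramp: one crossing
  expect_equal(cs$n_crossings, 1)
  expect_equal(cs$sd_interval_s, 0)

  ps <- peak_interval_stats(c(0, 1, 0, 1, 0), fs = 1)
  expect_equal(ps$n_peaks, 2)
  expect_equal(ps$mean_interval_s, 2)
  expect_equal(ps$sd_interval_s, 0)

  ps <- peak_interval_stats(1:10, fs = 1)
  expect_equal(ps$n_peaks, 0)

  ps <- peak_interval_stats(c(0, 1, 0, 2, 0, 1, 0), fs = 1)
  expect_equal(ps$n_peaks, 3)
  expect_equal(ps$mean_interval_s, 2)
  expect_equal(ps$sd_interval_s, 0)

  # plateau maxima count once, at the first plateau index
  ps <- peak_interval_stats(c(0, 1, 1, 1, 0, 1, 0), fs = 2)
  expect_equal(ps$n_peaks, 2)
  expect_equal(ps$mean_interval_s, 2)

  set.seed(24)
  for (i in 1:30) {
    x <- sample(c(-1, 1), sample(20:120, 1), replace = TRUE)
    fs <- sample(c(1, 50, 100), 1)
    got <- crossing_stats(x, fs); want <- oracle_crossings(x, fs)
    expect_equal(got$n_crossings, want$n)
    expect_equal(got$mean_interval_s, want$mean, tolerance = 1e-12)
    expect_equal(got$sd_interval_s, want$sd, tolerance = 1e-12)
    gp <- peak_interval_stats(x, fs); wp <- oracle_peaks(x, fs)
    expect_equal(gp$n_peaks, wp$n)
    expect_equal(gp$mean_interval_s, wp$mean, tolerance = 1e-12)
    expect_equal(gp$sd_interval_s, wp$sd, tolerance = 1e-12)
  }
})

test_that("basic statistics use population conventions", {
  b <- basic_stats(c(1, 1, 1))
  expect_equal(b$mean, 1)
  expect_equal(b$sd, 0)
  expect_true(is.nan(b$kurtosis))

  b <- basic_stats(c(-1, 1))
  expect_equal(b$mean, 0)
  expect_equal(b$sd, 1)
  expect_equal(b$rms, 1)

  set.seed(25)
  b <- basic_stats(rnorm(1e5))
  expect_equal(b$kurtosis, 3, tolerance = 0.1)
  expect_equal(b$skewness, 0, tolerance = 0.05)
})

test_that("the default catalog has 165 uniquely named entries incl. the key attributes", {
  cat <- feature_catalog()
  expect_equal(nrow(cat), 165)
  expect_false(anyDuplicated(cat$name) > 0)
  expect_true(all(c("SD1_GYROY", "SD2_GYROY", "Kur_GYROZ", "Skew_GYROZ",
                    "SDZCIL_ACCZ") %in% cat$name))
  expect_equal(sort(unique(cat$channel)),
               sort(c(imu_channel_names(), "MAGNITUDE")))
})

test_that("feature extraction is deterministic, complete, and consistently addressed", {
  rec <- make_test_recording(n = 1200)
  fv <- extract_features(rec)
  expect_length(fv, 165)
  expect_true(all(is.finite(fv)))
  expect_identical(unname(fv), unname(extract_features(rec)))

  expect_equal(fv[["SD1_GYROY"]],
               poincare_descriptors(rec$channels$GYRO_Y)$sd1)
  expect_equal(fv[["Kur_GYROZ"]],
               spectral_moments(rec$channels$GYRO_Z, 100)$kurt)
  expect_equal(fv[["SDZCIL_ACCZ"]],
               peak_interval_stats(rec$channels$ACC_Z, 100)$sd_interval_s)
  expect_equal(fv[["Mean_MAG"]],
               mean(sqrt(rec$channels$ACC_X^2 + rec$channels$ACC_Y^2 +
                           rec$channels$ACC_Z^2)))

  bad_cat <- feature_catalog()
  bad_cat$channel[1] <- "NOPE"
  expect_error(extract_features(rec, bad_cat), class = "hemigait_format_error")
})

test_that("undefined attributes are zeroed with a warning (missing policy)", {
  ch <- list(ACC_X = rep(0, 100), ACC_Y = rep(0, 100), ACC_Z = rep(0, 100),
             GYRO_X = rep(0, 100), GYRO_Y = sin(1:100), GYRO_Z = sin(1:100))
  rec <- imu_recording(ch, 100)
  expect_warning(fv <- extract_features(rec), "missing-value policy")
  expect_true(all(is.finite(fv)))
  expect_equal(fv[["TKur_ACCX"]], 0)
})

test_that("feature tables round-trip through CSV", {
  co <- simulate_cohort(2, 2, seed = 31)
  ds <- cohort_features(co)
  expect_equal(dim(ds$matrix), c(8, 165))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ds, path)
  back <- read_feature_table(path)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$subject_ids, ds$subject_ids)
  expect_equal(back$matrix, ds$matrix, tolerance = 1e-12)
})
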