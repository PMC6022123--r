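test_that("simulation is deterministic in the profile seed", {
  p <- gait_profile("hemiplegic", seed = 11)
  r1 <- simulate_recording(p)
  r2 <- simulate_recording(p)
  expect_identical(r1$channels, r2$channels)
  p$seed <- 12L
  r3 <- simulate_recording(p)
  expect_false(identical(r1$channels, r3$channels))
})

test_that("a clean symmetric profile produces equal left and right steps", {
  p <- gait_profile("normal", asymmetry_ratio = 0, spike_rate_hz = 0,
                    noise_sd = 0, step_jitter_cv = 0, seed = 1)
  rec <- simulate_recording(p)
  # alternating lateral sway: equal magnitude on both sides
  expect_equal(max(rec$channels$ACC_X), -min(rec$channels$ACC_X),
               tolerance = 1e-8)
  expect_equal(max(rec$channels$GYRO_Y), -min(rec$channels$GYRO_Y),
               tolerance = 1e-8)
  # vertical pulses identical every step: per-step maxima all equal
  pk <- peak_interval_stats(rec$channels$ACC_Y, rec$sampling_rate_hz)
  expect_equal(pk$n_peaks, p$n_steps)
})

test_that("sample count equals round((standby + total step time) * fs)", {
  p <- gait_profile("normal", step_jitter_cv = 0, n_steps = 23,
                    step_period_s = 1.07, seed = 2)
  rec <- simulate_recording(p, sampling_rate_hz = 100, standby_s = 3)
  expect_equal(n_samples(rec), round((3 + 23 * 1.07) * 100))
})

test_that("profile invariants are enforced", {
  expect_error(gait_profile("normal", asymmetry_ratio = 0.2),
               class = "hemigait_validation_error")
  expect_error(gait_profile("normal", spike_rate_hz = 0.5),
               class = "hemigait_validation_error")
  expect_error(gait_profile("hemiplegic", n_steps = 3),
               class = "hemigait_validation_error")
  expect_error(gait_profile("hemiplegic", asymmetry_ratio = 1.2),
               class = "hemigait_validation_error")
})

test_that("cohort simulation yields labeled parallel walks, reproducibly", {
  co <- simulate_cohort(15, 20, seed = 1)
  expect_length(co$recordings, 70)
  expect_equal(sum(co$labels), 40)
  expect_equal(length(unique(co$subject_ids)), 35)
  # both walks of a subject share the profile label
  for (s in unique(co$subject_ids)) {
    expect_length(unique(co$labels[co$subject_ids == s]), 1)
  }
  co_b <- simulate_cohort(15, 20, seed = 1)
  expect_identical(co_b$recordings[[7]]$channels, co$recordings[[7]]$channels)
  co_c <- simulate_cohort(15, 20, seed = 2)
  expect_false(identical(co_c$recordings[[7]]$channels,
                         co$recordings[[7]]$channels))

  co0 <- simulate_cohort(0, 5, seed = 3)
  expect_true(all(co0$labels == 1))

  bad <- default_param_ranges()
  bad$normal$step_period_s <- numeric(0)
  expect_error(simulate_cohort(2, 2, bad, seed = 1),
               class = "hemigait_validation_error")
})

test_that("hemiplegic generator with no asymmetry and no spikes matches the normal one", {
  # with rho = 0 and lambda = 0 the two labels drive identical generative
  # paths; given the same seed the recordings coincide exactly, which implies
  # distributional identity over any number of seeds
  for (s in c(5, 6, 7)) {
    pn <- gait_profile("normal", double_support_frac = 0.2,
                       step_jitter_cv = 0.03, seed = s)
    ph <- gait_profile("hemiplegic", asymmetry_ratio = 0, spike_rate_hz = 0,
                       double_support_frac = 0.2, step_period_s = 1.1,
                       step_jitter_cv = 0.03, seed = s)
    expect_identical(simulate_recording(pn)$channels,
                     simulate_recording(ph)$channels)
  }
})

test_that("asymmetry and compensation spikes raise yaw Poincare SD1", {
  # Monte-Carlo comparison on matched profiles, 200 seeds per arm
  sd1_of <- function(rho, lam, seed) {
    p <- gait_profile("hemiplegic", asymmetry_ratio = rho, spike_rate_hz = lam,
                      n_steps = 40, seed = seed)
    rec <- simulate_recording(p)
    seg <- trim_standby(rec)
    cal <- calibrate_offsets(seg$walking, seg$standby)
    poincare_descriptors(cal$channels$GYRO_Y)$sd1
  }
  seeds <- 1:200
  hemi <- vapply(seeds, function(s) sd1_of(0.4, 0.5, 1000 + s), numeric(1))
  norm <- vapply(seeds, function(s) sd1_of(0, 0, 1000 + s), numeric(1))
  tt <- t.test(hemi, norm)
  expect_gt(mean(hemi), mean(norm))
  expect_lt(tt$p.value, 0.01)
})

test_that("discriminative feature means move monotonically in rho and lambda", {
  feat_means <- function(rho, lam, n = 80) {
    sd1 <- kur <- numeric(n)
    for (i in seq_len(n)) {
      p <- gait_profile("hemiplegic", asymmetry_ratio = rho,
                        spike_rate_hz = lam, seed = 3000 + i)
      rec <- simulate_recording(p)
      seg <- trim_standby(rec)
      cal <- calibrate_offsets(seg$walking, seg$standby)
      sd1[i] <- poincare_descriptors(cal$channels$GYRO_Y)$sd1
      kur[i] <- spectral_moments(cal$channels$GYRO_Z,
                                 cal$sampling_rate_hz)$kurt
    }
    c(sd1 = mean(sd1), kur = mean(kur))
  }
  by_rho <- sapply(c(0, 0.3, 0.6), feat_means, lam = 0)
  by_lam <- sapply(c(0, 0.5, 1), feat_means, rho = 0)
  # SD1 of yaw increases with the paretic deficit and with the spike rate
  expect_true(all(diff(by_rho["sd1", ]) > 0))
  expect_true(all(diff(by_lam["sd1", ]) > 0))
  # spectral kurtosis of roll: spikes add broadband mass, lowering the
  # peakedness of the spectral distribution; asymmetry sharpens it
  expect_true(all(diff(by_lam["kur", ]) < 0))
  expect_gt(by_rho["kur", 3], by_rho["kur", 1])
})

test_that("cohort directories round-trip through write_cohort/load_cohort", {
  co <- simulate_cohort(2, 2, seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(file.exists(file.path(dir, "profiles.json")))
  back <- load_cohort(dir)
  expect_equal(back$labels, co$labels)
  expect_equal(back$recording_ids, co$recording_ids)
  expect_equal(back$recordings[[3]]$channels, co$recordings[[3]]$channels)
})
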