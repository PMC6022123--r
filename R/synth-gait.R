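#' Gait profile for the synthetic trunk-IMU generator
#'
#' A `gait_profile` parameterises one simulated subject's walk. The generator
#' emulates the statistical structure that separates hemiplegic from normal
#' trunk signals: periodic alternating steps, a relative amplitude deficit and
#' yaw over-rotation on the paretic side, amplitude flattening during double
#' support, occasional abrupt compensation spikes, cadence jitter, and
#' additive sensor noise.
#'
#' @param label `"normal"` or `"hemiplegic"`.
#' @param step_period_s nominal step duration in seconds.
#' @param n_steps number of steps in the walk (>= 4).
#' @param amp_vertical,amp_lateral,amp_longitudinal acceleration amplitudes
#'   (g) of the vertical raised-cosine pulse, the alternating lateral
#'   half-sine, and the foot-contact impulse.
#' @param gyro_amp yaw angular-velocity amplitude (deg/s).
#' @param asymmetry_ratio paretic-side deficit `rho` in `[0, 1)`: paretic-step
#'   acceleration amplitudes are scaled by `1 - rho` and paretic yaw by
#'   `1 + rho`. Must be 0 for normal profiles.
#' @param double_support_frac fraction of each step flattened (amplitude
#'   x 0.2) at its end, emulating double support.
#' @param spike_rate_hz Poisson rate `lambda` (events/s) of compensation
#'   spikes; each spike is a 100 ms biphasic pulse added to all gyroscope
#'   channels (amplitude `spike_amp * gyro_amp`) and to lateral acceleration
#'   (amplitude `spike_amp * amp_lateral`). Must be 0 for normal profiles.
#' @param spike_amp dimensionless spike amplitude multiplier.
#' @param step_jitter_cv coefficient of variation of the lognormal step-
#'   duration jitter.
#' @param noise_sd standard deviation of the additive white Gaussian sensor
#'   noise applied to every channel.
#' @param paretic_side `"left"` or `"right"`: which side carries the deficit
#'   (hemiplegia affects either side; cohorts mix both).
#' @param seed integer seed; the simulated recording is a deterministic
#'   function of the profile including the seed.
#' @return A validated object of class `gait_profile`.
#' @export
gait_profile <- function(label = c("normal", "hemiplegic"),
                         step_period_s = if (label == "hemiplegic") 1.4 else 1.1,
                         n_steps = 30L,
                         amp_vertical = 0.3, amp_lateral = 0.15,
                         amp_longitudinal = 0.2, gyro_amp = 60,
                         asymmetry_ratio = if (label == "hemiplegic") 0.4 else 0,
                         double_support_frac = if (label == "hemiplegic") 0.35 else 0.2,
                         spike_rate_hz = if (label == "hemiplegic") 0.5 else 0,
                         spike_amp = 1.5,
                         step_jitter_cv = if (label == "hemiplegic") 0.1 else 0.03,
                         noise_sd = 0.03, paretic_side = c("left", "right"),
                         seed = 1L) {
  label <- match.arg(label)
  paretic_side <- match.arg(paretic_side)
  p <- structure(as.list(environment()), class = "gait_profile")
  validate_gait_profile(p)
}

validate_gait_profile <- function(p) {
  if (!inherits(p, "gait_profile")) abort_hg("not a gait_profile", "hemigait_validation_error")
  num_ok <- function(x, lo = 0) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= lo
  checks <- c(
    step_period = num_ok(p$step_period_s) && p$step_period_s > 0,
    n_steps = num_ok(p$n_steps, 4),
    amps = all(vapply(p[c("amp_vertical", "amp_lateral", "amp_longitudinal",
                          "gyro_amp", "spike_amp", "noise_sd",
                          "spike_rate_hz", "step_jitter_cv")],
                      num_ok, logical(1))),
    rho = num_ok(p$asymmetry_ratio) && p$asymmetry_ratio < 1,
    ds = num_ok(p$double_support_frac) && p$double_support_frac < 1
  )
  if (!all(checks)) {
    abort_hg(paste0("invalid gait_profile field(s): ",
                    paste(names(checks)[!checks], collapse = ", ")),
             "hemigait_validation_error")
  }
  if (p$label == "normal" &&
      (p$asymmetry_ratio != 0 || p$spike_rate_hz != 0 ||
       p$double_support_frac > 0.25 || p$step_jitter_cv > 0.1)) {
    abort_hg(paste0("normal profile requires asymmetry_ratio = 0, ",
                    "spike_rate_hz = 0, double_support_frac <= 0.25, ",
                    "step_jitter_cv <= 0.1"),
             "hemigait_validation_error")
  }
  p
}

#' Simulate one trunk inertial recording from a gait profile
#'
#' Steps alternate right (odd) / left (even); the left side is taken as
#' paretic for hemiplegic profiles. Per step the deterministic waveforms are:
#' vertical acceleration, a raised-cosine pulse (one per step, i.e. two per
#' stride); lateral acceleration, an alternating-sign half-sine; longitudinal
#' acceleration, an impulse-plus-exponential-decay at foot contact; yaw
#' angular velocity (`GYRO_Y`), an alternating half-sine with paretic
#' over-rotation. `GYRO_X` and `GYRO_Z` are scaled, phase-shifted copies of
#' the yaw waveform (their channel noise is drawn independently). The final
#' `double_support_frac` of every step is amplitude-flattened (x 0.2). Step
#' durations carry lognormal jitter, compensation spikes arrive as a Poisson
#' process, white Gaussian noise is added to every channel, and a standby pad
#' (noise plus a constant +1 g gravity projection on `ACC_Y`, present
#' throughout the recording until calibration) is prepended.
#'
#' @param profile a [gait_profile()].
#' @param sampling_rate_hz sampling rate (default 100 Hz).
#' @param standby_s length of the prepended quiet standing pad in seconds.
#' @return An [imu_recording()], deterministic given the profile (seed
#'   included).
#' @export
simulate_recording <- function(profile, sampling_rate_hz = 100, standby_s = 3) {
  validate_gait_profile(profile)
  fs <- sampling_rate_hz
  p <- profile
  with_local_seed(p$seed, {
    # jittered step durations (lognormal, mean 1, given CV)
    cv <- p$step_jitter_cv
    if (cv > 0) {
      s2 <- log(1 + cv^2)
      jit <- stats::rlnorm(p$n_steps, meanlog = -s2 / 2, sdlog = sqrt(s2))
    } else {
      jit <- rep(1, p$n_steps)
    }
    dur <- p$step_period_s * jit
    n <- as.integer(round((standby_s + sum(dur)) * fs))
    t <- (seq_len(n) - 1) / fs
    starts <- standby_s + c(0, cumsum(dur[-p$n_steps]))
    walk_t0 <- standby_s
    walk_t1 <- standby_s + sum(dur)

    # per-sample step index (0 = standby / past end)
    k <- findInterval(t, c(starts, walk_t1))
    k[t >= walk_t1] <- 0L
    in_step <- k > 0L
    u <- numeric(n)                                   # phase in [0,1)
    u[in_step] <- (t[in_step] - starts[k[in_step]]) / dur[k[in_step]]

    left_steps <- (seq_len(p$n_steps) %% 2L) == 0L    # odd = right, even = left
    paretic <- if (identical(p$paretic_side, "right")) !left_steps else left_steps
    hemi <- p$label == "hemiplegic"
    rho <- if (hemi) p$asymmetry_ratio else 0
    a_scale <- ifelse(paretic, 1 - rho, 1)            # acceleration deficit
    g_scale <- ifelse(paretic, 1 + rho, 1)            # yaw over-rotation
    side <- ifelse(left_steps, -1, 1)                 # sway sign follows step side

    amp <- function(per_step) { out <- numeric(n); out[in_step] <- per_step[k[in_step]]; out }
    ak <- amp(a_scale); gk <- amp(g_scale); sk <- amp(side)
    # double-support flattening of the step tail
    flat <- rep(1, n)
    flat[in_step & u > (1 - p$double_support_frac)] <- 0.2

    acc_y <- p$amp_vertical * ak * 0.5 * (1 - cos(2 * pi * u)) * in_step * flat
    acc_x <- p$amp_lateral * ak * sk * sin(pi * u) * in_step * flat
    t_in <- numeric(n)
    t_in[in_step] <- t[in_step] - starts[k[in_step]]
    acc_z <- p$amp_longitudinal * ak * exp(-t_in / 0.08) * in_step * flat
    yaw <- p$gyro_amp * gk * sk * sin(pi * u) * in_step * flat

    # zero net impulse per step on sway and yaw: over a straight walk the
    # trunk returns laterally and keeps heading, so lateral acceleration and
    # yaw rate integrate to ~0 per step; asymmetry must live in the waveform
    # shape, not in a DC offset
    step_of <- k
    for (kk in seq_len(p$n_steps)) {
      sel <- which(step_of == kk)
      if (length(sel)) {
        acc_x[sel] <- acc_x[sel] - mean(acc_x[sel])
        yaw[sel] <- yaw[sel] - mean(yaw[sel])
      }
    }

    shift_by <- function(x, lag) {
      lag <- as.integer(lag)
      if (lag <= 0L) return(x)
      c(numeric(lag), x[seq_len(length(x) - lag)])
    }
    gyro_x <- 0.6 * shift_by(yaw, round(0.25 * p$step_period_s * fs))
    gyro_z <- 0.8 * shift_by(yaw, round(0.40 * p$step_period_s * fs))

    # compensation spikes: biphasic 100 ms pulses on gyros + lateral acc
    if (hemi && p$spike_rate_hz > 0) {
      n_spk <- stats::rpois(1, p$spike_rate_hz * (walk_t1 - walk_t0))
      if (n_spk > 0) {
        at <- stats::runif(n_spk, walk_t0, walk_t1 - 0.1)
        sgn <- sample(c(-1, 1), n_spk, replace = TRUE)
        for (j in seq_len(n_spk)) {
          i0 <- as.integer(round(at[j] * fs)) + 1L
          len <- as.integer(round(0.1 * fs))
          idx <- i0:min(i0 + len - 1L, n)
          pulse <- sgn[j] * sin(2 * pi * seq_along(idx) / len)
          yaw[idx] <- yaw[idx] + p$spike_amp * p$gyro_amp * pulse
          gyro_x[idx] <- gyro_x[idx] + p$spike_amp * p$gyro_amp * pulse
          gyro_z[idx] <- gyro_z[idx] + p$spike_amp * p$gyro_amp * pulse
          acc_x[idx] <- acc_x[idx] + p$spike_amp * p$amp_lateral * pulse
        }
      }
    }

    acc_y <- acc_y + 1                                # gravity projection, removed by calibration
    ch <- list(ACC_X = acc_x, ACC_Y = acc_y, ACC_Z = acc_z,
               GYRO_X = gyro_x, GYRO_Y = yaw, GYRO_Z = gyro_z)
    if (p$noise_sd > 0) {
      ch <- lapply(ch, function(x) x + stats::rnorm(n, sd = p$noise_sd))
    }
    imu_recording(ch, fs, subject_id = "sim",
                  units = c(acc = "g", gyro = "deg/s"))
  })
}

#' Default per-class parameter ranges for cohort simulation
#'
#' Each entry is a `c(lo, hi)` uniform range from which a subject's profile
#' parameter is drawn. Hemiplegic subjects walk slower with shorter strides
#' (more steps over the same 20 m), show a paretic-side deficit, longer double
#' support, higher cadence variability, and compensation spikes; cadence
#' ranges overlap between classes because slow normal walkers and mildly
#' affected patients do in practice.
#'
#' @return Named list with elements `normal` and `hemiplegic`, each a named
#'   list of ranges.
#' @export
default_param_ranges <- function() {
  list(
    normal = list(
      step_period_s = c(1.0, 1.25), n_steps = c(26, 34),
      amp_vertical = c(0.25, 0.40), amp_lateral = c(0.10, 0.20),
      amp_longitudinal = c(0.15, 0.25), gyro_amp = c(40, 70),
      asymmetry_ratio = c(0, 0), double_support_frac = c(0.15, 0.25),
      spike_rate_hz = c(0, 0), spike_amp = c(0, 0),
      step_jitter_cv = c(0.02, 0.05), noise_sd = c(0.02, 0.04)
    ),
    hemiplegic = list(
      step_period_s = c(1.2, 1.5), n_steps = c(28, 40),
      amp_vertical = c(0.18, 0.35), amp_lateral = c(0.12, 0.25),
      amp_longitudinal = c(0.12, 0.22), gyro_amp = c(40, 80),
      asymmetry_ratio = c(0.3, 0.5), double_support_frac = c(0.30, 0.45),
      spike_rate_hz = c(0.3, 0.7), spike_amp = c(1.0, 2.0),
      step_jitter_cv = c(0.07, 0.15), noise_sd = c(0.02, 0.04)
    )
  )
}

#' Simulate a labeled cohort of walks
#'
#' Draws one profile per subject from the per-class parameter ranges and
#' simulates two walks per subject (out and back along the corridor) sharing
#' the profile but using different sub-seeds. Sub-seeds are derived per
#' (subject, walk) from the master seed, so any cohort element is reproducible
#' on its own.
#'
#' @param n_normal,n_hemi numbers of normal and hemiplegic subjects.
#' @param param_ranges per-class parameter ranges as from
#'   [default_param_ranges()].
#' @param seed master seed.
#' @param walks_per_subject walks simulated per subject (default 2).
#' @param sampling_rate_hz passed to [simulate_recording()].
#' @return An object of class `gait_cohort`: list with `recordings` (list of
#'   [imu_recording()]), `labels` (0 = normal, 1 = hemiplegic), `subject_ids`,
#'   `walk`, `recording_ids`, and `profiles`, all parallel.
#' @export
simulate_cohort <- function(n_normal, n_hemi, param_ranges = default_param_ranges(),
                            seed = 1L, walks_per_subject = 2L,
                            sampling_rate_hz = 100) {
  stopifnot(n_normal >= 0, n_hemi >= 0, n_normal + n_hemi > 0)
  for (cls in c("normal", "hemiplegic")) {
    rg <- param_ranges[[cls]]
    if (is.null(rg) || !length(rg)) abort_hg("empty parameter ranges", "hemigait_validation_error")
    bad <- !vapply(rg, function(r) length(r) == 2L && all(is.finite(r)) && r[2] >= r[1],
                   logical(1))
    if (any(bad)) {
      abort_hg(paste0("malformed range(s) for ", cls, ": ",
                      paste(names(rg)[bad], collapse = ", ")),
               "hemigait_validation_error")
    }
  }
  n_subj <- n_normal + n_hemi
  labels_subj <- rep(c("normal", "hemiplegic"), c(n_normal, n_hemi))
  seeds <- derive_seeds(seed, n_subj * (walks_per_subject + 1L))
  dim(seeds) <- c(n_subj, walks_per_subject + 1L)

  recordings <- list(); labels <- integer(0); subject_ids <- character(0)
  walk <- integer(0); profiles <- list()
  for (i in seq_len(n_subj)) {
    cls <- labels_subj[i]
    rg <- param_ranges[[cls]]
    drawn <- with_local_seed(seeds[i, 1L], {
      list(par = vapply(rg, function(r) stats::runif(1, r[1], r[2]), numeric(1)),
           side = sample(c("left", "right"), 1L))
    })
    draw <- drawn$par
    sid <- sprintf("S%02d", i)
    prof <- gait_profile(
      label = cls,
      step_period_s = draw[["step_period_s"]],
      n_steps = as.integer(round(draw[["n_steps"]])),
      amp_vertical = draw[["amp_vertical"]],
      amp_lateral = draw[["amp_lateral"]],
      amp_longitudinal = draw[["amp_longitudinal"]],
      gyro_amp = draw[["gyro_amp"]],
      asymmetry_ratio = draw[["asymmetry_ratio"]],
      double_support_frac = draw[["double_support_frac"]],
      spike_rate_hz = draw[["spike_rate_hz"]],
      spike_amp = draw[["spike_amp"]],
      step_jitter_cv = draw[["step_jitter_cv"]],
      noise_sd = draw[["noise_sd"]],
      paretic_side = drawn$side,
      seed = seeds[i, 2L]
    )
    profiles[[sid]] <- prof
    for (w in seq_len(walks_per_subject)) {
      pw <- prof
      pw$seed <- seeds[i, w + 1L]
      rec <- simulate_recording(pw, sampling_rate_hz = sampling_rate_hz)
      rec$subject_id <- sid
      recordings[[length(recordings) + 1L]] <- rec
      labels <- c(labels, as.integer(cls == "hemiplegic"))
      subject_ids <- c(subject_ids, sid)
      walk <- c(walk, w)
    }
  }
  structure(
    list(recordings = recordings, labels = labels, subject_ids = subject_ids,
         walk = walk,
         recording_ids = sprintf("%s_w%d", subject_ids, walk),
         profiles = profiles),
    class = "gait_cohort"
  )
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d walks (%d hemiplegic, %d normal) from %d subjects\n",
              length(x$recordings), sum(x$labels), sum(x$labels == 0),
              length(x$profiles)))
  invisible(x)
}

#' Write a simulated cohort to a directory
#'
#' Writes one recording CSV per walk plus `labels.csv`
#' (`recording_id,subject_id,walk,label`) and `profiles.json`.
#'
#' @param cohort a `gait_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$recordings)) {
    write_recording(cohort$recordings[[i]],
                    file.path(dir, paste0(cohort$recording_ids[i], ".csv")))
  }
  utils::write.csv(
    data.frame(recording_id = cohort$recording_ids,
               subject_id = cohort$subject_ids,
               walk = cohort$walk, label = cohort$labels),
    file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    lapply(cohort$profiles, function(p) unclass(p)),
    file.path(dir, "profiles.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
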