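#' Six-channel trunk inertial recording
#'
#' Container for one walk recorded by a trunk-worn inertial module: three
#' acceleration axes and three angular-velocity axes sampled at a fixed rate.
#' The axis convention is the lumbar-mounted one used throughout the package:
#' `+x` lateral, `+y` vertical, `-z` longitudinal, so `GYRO_Y` is angular
#' velocity around the vertical axis (yaw) and `GYRO_Z` around the
#' longitudinal axis (roll about the walking direction).
#'
#' @param channels a named list or data.frame with numeric elements
#'   `ACC_X, ACC_Y, ACC_Z, GYRO_X, GYRO_Y, GYRO_Z`, all the same length
#'   (at least 2 samples), all finite. Acceleration in g or m/s^2, angular
#'   velocity in deg/s; units are metadata, never rescaled internally.
#' @param sampling_rate_hz positive sampling rate in samples per second.
#' @param subject_id character label for the subject/walk.
#' @param annotation optional character scalar, e.g. `"walking"` or
#'   `"standby"`, describing what the segment contains.
#' @param units optional named character vector of unit labels.
#'
#' @return An object of class `imu_recording`: a list with elements
#'   `channels` (named list of six equal-length numeric vectors),
#'   `sampling_rate_hz`, `subject_id`, `annotation`, `units`.
#' @seealso [read_recording()], [write_recording()], [trim_standby()],
#'   [calibrate_offsets()]
#' @export
imu_recording <- function(channels, sampling_rate_hz, subject_id = "anon",
                          annotation = NULL, units = NULL) {
  channels <- as.list(channels)
  rec <- structure(
    list(
      channels = channels[imu_channel_names()],
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      subject_id = as.character(subject_id),
      annotation = annotation,
      units = units
    ),
    class = "imu_recording"
  )
  validate_imu_recording(rec)
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording> subject=%s  %d samples @ %g Hz  (%.2f s)%s\n",
    x$subject_id, n_samples(x), x$sampling_rate_hz, duration_s(x),
    if (!is.null(x$annotation)) paste0("  [", x$annotation, "]") else ""
  ))
  invisible(x)
}

#' Channel names of the six-axis inertial data model
#' @return Character vector of the six canonical channel names.
#' @export
imu_channel_names <- function() {
  c("ACC_X", "ACC_Y", "ACC_Z", "GYRO_X", "GYRO_Y", "GYRO_Z")
}

#' @rdname imu_recording
#' @param rec an `imu_recording`.
#' @export
n_samples <- function(rec) length(rec$channels[[1L]])

#' @rdname imu_recording
#' @export
duration_s <- function(rec) n_samples(rec) / rec$sampling_rate_hz

validate_imu_recording <- function(rec) {
  if (!inherits(rec, "imu_recording")) {
    abort_hg("not an imu_recording", "hemigait_validation_error")
  }
  ch <- rec$channels
  missing <- setdiff(imu_channel_names(), names(ch))
  if (length(missing)) {
    abort_hg(
      paste0("missing channel(s): ", paste(missing, collapse = ", ")),
      "hemigait_format_error"
    )
  }
  lens <- vapply(ch, length, integer(1))
  if (length(unique(lens)) != 1L || lens[1L] < 2L) {
    abort_hg("all 6 channels must be equal length >= 2",
             "hemigait_validation_error")
  }
  if (!is.finite(rec$sampling_rate_hz) || rec$sampling_rate_hz <= 0) {
    abort_hg("sampling_rate_hz must be a positive real",
             "hemigait_validation_error")
  }
  if (!all(vapply(ch, function(v) all(is.finite(v)), logical(1)))) {
    abort_hg("non-finite samples in channel data", "hemigait_validation_error")
  }
  rec
}

# Column header used in the delimited on-disk representation.
recording_file_columns <- function() {
  c("t", "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
}

#' Read a six-channel inertial recording from delimited text
#'
#' The expected layout is one row per sample with a header naming a time
#' column `t` (seconds) and the six signal columns
#' `acc_x,acc_y,acc_z,gyro_x,gyro_y,gyro_z`. Lines starting with `#` are
#' metadata comments; `# subject_id: <id>` is recognised and carried into the
#' returned object. The sampling rate is inferred from the median inter-sample
#' interval of the time column unless supplied in `format_spec`; a supplied
#' rate disagreeing with the inferred one by more than 1% is an error.
#'
#' @param path path to the file.
#' @param format_spec optional list with elements `delimiter` (default `","`),
#'   `decimal` (default `"."`), and `sampling_rate_hz` (optional override that
#'   is cross-checked against the time column).
#' @return A validated [imu_recording()].
#' @export
read_recording <- function(path, format_spec = list()) {
  if (!file.exists(path)) {
    abort_hg(paste0("file not found: ", path), "hemigait_format_error")
  }
  delim <- format_spec$delimiter %||% ","
  dec <- format_spec$decimal %||% "."
  header_lines <- grep("^#", readLines(path, n = 20L, warn = FALSE), value = TRUE)
  subject_id <- "anon"
  m <- regmatches(header_lines, regexec("^#\\s*subject_id:\\s*(\\S+)", header_lines))
  hit <- Filter(function(x) length(x) == 2L, m)
  if (length(hit)) subject_id <- hit[[1L]][2L]

  dt <- data.table::fread(path, sep = delim, dec = dec, header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  need <- recording_file_columns()
  if (!all(need %in% names(dt))) {
    abort_hg(
      paste0("expected columns ", paste(need, collapse = ","),
             "; found ", paste(names(dt), collapse = ",")),
      "hemigait_format_error"
    )
  }
  tcol <- as.numeric(dt[["t"]])
  if (length(tcol) < 2L) {
    abort_hg("recording needs at least 2 samples", "hemigait_validation_error")
  }
  if (any(!is.finite(tcol)) || any(diff(tcol) <= 0)) {
    abort_hg("time column must be finite and strictly increasing",
             "hemigait_validation_error")
  }
  fs_inferred <- 1 / stats::median(diff(tcol))
  # snap to an integer rate when the time column agrees to 1e-6 relative
  # (text round-tripping perturbs the inter-sample interval in the last ulp)
  if (abs(fs_inferred - round(fs_inferred)) < 1e-6 * fs_inferred) {
    fs_inferred <- round(fs_inferred)
  }
  fs <- format_spec$sampling_rate_hz %||% fs_inferred
  if (abs(fs - fs_inferred) / fs_inferred > 0.01) {
    abort_hg(sprintf(
      "declared sampling rate %.4g Hz disagrees with time column (%.4g Hz) by > 1%%",
      fs, fs_inferred
    ), "hemigait_validation_error")
  }
  ch <- lapply(need[-1L], function(cn) as.numeric(dt[[cn]]))
  names(ch) <- imu_channel_names()
  imu_recording(ch, sampling_rate_hz = fs, subject_id = subject_id)
}

#' Write a recording to delimited text
#'
#' Writes the inverse of [read_recording()]: a `#` metadata header with the
#' subject id, then one row per sample with the time column reconstructed
#' from the sampling rate (`t = (0:(n-1))/fs`), at full double precision so
#' that write-then-read round-trips the samples bit-identically.
#'
#' @param rec a valid [imu_recording()].
#' @param path output path.
#' @param format_spec optional list with `delimiter` (default `","`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format_spec = list()) {
  validate_imu_recording(rec)
  delim <- format_spec$delimiter %||% ","
  n <- n_samples(rec)
  df <- data.frame(t = (seq_len(n) - 1) / rec$sampling_rate_hz)
  sig <- as.data.frame(rec$channels)
  names(sig) <- recording_file_columns()[-1L]
  df <- cbind(df, sig)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# subject_id: ", rec$subject_id), con)
  if (!is.null(rec$units)) {
    writeLines(paste0("# units: ", paste(names(rec$units), rec$units,
                                         sep = "=", collapse = " ")), con)
  }
  # full-precision decimal rendering (17 significant digits round-trips doubles)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = delim, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Split a recording into standby and walking segments
#'
#' The module records continuously, so each file starts (and may end) with the
#' subject standing still; those segments carry the gravity projection and
#' gyro bias and are used only for calibration. A moving-window standard
#' deviation of the acceleration magnitude classifies each sample as active or
#' quiet; the walking segment is the contiguous span between the first and the
#' last active window, and the leading/trailing quiet spans are concatenated
#' into the standby segment.
#'
#' @param rec an [imu_recording()].
#' @param standby_window_s window length in seconds for the moving SD
#'   (default 1 s).
#' @param activity_threshold SD threshold (same units as acceleration) above
#'   which a window counts as active (default 0.05).
#' @return A list with elements `walking` and `standby`, both
#'   `imu_recording`s (`standby` is `NULL` when the recording has no quiet
#'   samples).
#' @export
trim_standby <- function(rec, standby_window_s = 1, activity_threshold = 0.05) {
  validate_imu_recording(rec)
  n <- n_samples(rec)
  fs <- rec$sampling_rate_hz
  if (duration_s(rec) <= standby_window_s) {
    abort_hg("recording shorter than the standby window",
             "hemigait_validation_error")
  }
  mag <- sqrt(rec$channels$ACC_X^2 + rec$channels$ACC_Y^2 + rec$channels$ACC_Z^2)
  w <- max(2L, as.integer(round(standby_window_s * fs)))
  # centered moving SD via moving moments
  csum <- c(0, cumsum(mag))
  csum2 <- c(0, cumsum(mag^2))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- hi - lo + 1
  mu <- (csum[hi + 1L] - csum[lo]) / cnt
  v <- pmax((csum2[hi + 1L] - csum2[lo]) / cnt - mu^2, 0)
  active <- sqrt(v) >= activity_threshold
  if (!any(active)) {
    abort_hg("no walking detected: recording entirely below activity threshold",
             "hemigait_no_walking_error")
  }
  i0 <- which(active)[1L]
  i1 <- which(active)[length(which(active))]
  walk_idx <- i0:i1
  stand_idx <- setdiff(seq_len(n), walk_idx)
  walking <- imu_recording(
    lapply(rec$channels, `[`, walk_idx),
    rec$sampling_rate_hz, rec$subject_id, annotation = "walking",
    units = rec$units
  )
  standby <- NULL
  if (length(stand_idx) >= 2L) {
    standby <- imu_recording(
      lapply(rec$channels, `[`, stand_idx),
      rec$sampling_rate_hz, rec$subject_id, annotation = "standby",
      units = rec$units
    )
  }
  list(walking = walking, standby = standby)
}

#' Remove static offsets estimated from a standby segment
#'
#' Subtracts the per-channel mean of the quiet (standing) segment from every
#' channel of `rec`. On the accelerometer this removes the gravity projection
#' onto each axis; on the gyroscope it removes the constant rate bias. Sample
#' count and sampling rate are preserved.
#'
#' @param rec the recording to calibrate (typically the walking segment).
#' @param standby an `imu_recording` of quiet standing, at least 1 s long.
#' @return The calibrated `imu_recording`.
#' @export
calibrate_offsets <- function(rec, standby) {
  validate_imu_recording(rec)
  validate_imu_recording(standby)
  if (duration_s(standby) < 1) {
    abort_hg("standby segment shorter than 1 s; cannot estimate offsets",
             "hemigait_validation_error")
  }
  offs <- vapply(standby$channels, mean, numeric(1))
  ch <- mapply(function(x, o) x - o, rec$channels, offs[names(rec$channels)],
               SIMPLIFY = FALSE)
  imu_recording(ch, rec$sampling_rate_hz, rec$subject_id,
                annotation = rec$annotation, units = rec$units)
}
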