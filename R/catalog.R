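# The default attribute catalog: 6 channels x 27 attributes + 3 acceleration-
# magnitude attributes = 165, computed on the whole walk (no step detection).
#
# Per channel, in order:
#   time (15):     Mean, Max, Min, Range, SD, Var, RMS, TKur, TSkew,
#                  NZC, MZCI, SDZCI  (zero crossings: count, mean/SD interval),
#                  NLM, MZCIL, SDZCIL (local maxima: count, mean/SD interval)
#   spectral (7):  DF (dominant freq), CF (centroid), BW (bandwidth),
#                  Skew, Kur (spectral shape moments), SpEnt (entropy),
#                  TP (total power)
#   poincare (3):  SD1, SD2, SDR (SD1/SD2, 0/0 -> 0)
#   autocorr (2):  AC1 (lag-1), ACP (first nonzero-lag autocorrelation peak)
# Magnitude (3):   Mean_MAG, SD_MAG, Max_MAG on sqrt(ax^2+ay^2+az^2).

catalog_channel_token <- function(channel) gsub("_", "", channel)

time_stat_names <- function() {
  c("Mean", "Max", "Min", "Range", "SD", "Var", "RMS", "TKur", "TSkew",
    "NZC", "MZCI", "SDZCI", "NLM", "MZCIL", "SDZCIL")
}
spectral_stat_names <- function() c("DF", "CF", "BW", "Skew", "Kur", "SpEnt", "TP")
poincare_stat_names <- function() c("SD1", "SD2", "SDR")
autocorr_stat_names <- function() c("AC1", "ACP")

#' The default 165-attribute feature catalog
#'
#' An ordered table declaring every attribute extracted from a walk: its
#' unique name, source channel (one of the six axes or `MAGNITUDE`), family
#' (`time`, `spectral`, `poincare`, `autocorr`), and extractor statistic.
#' Attribute names are `<Stat>_<CHANNEL>`, e.g. `SD1_GYROY` is the Poincare
#' SD1 of the yaw angular velocity and `Kur_GYROZ` the spectral kurtosis of
#' the angular velocity around the longitudinal axis.
#'
#' @return A data.frame with columns `name`, `channel`, `family`, `stat`,
#'   one row per attribute; exactly 165 rows.
#' @export
feature_catalog <- function() {
  rows <- list()
  for (ch in imu_channel_names()) {
    tok <- catalog_channel_token(ch)
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(c(time_stat_names(), spectral_stat_names(),
                      poincare_stat_names(), autocorr_stat_names()), "_", tok),
      channel = ch,
      family = rep(c("time", "spectral", "poincare", "autocorr"),
                   c(15L, 7L, 3L, 2L)),
      stat = c(time_stat_names(), spectral_stat_names(),
               poincare_stat_names(), autocorr_stat_names())
    )
  }
  rows[[length(rows) + 1L]] <- data.frame(
    name = c("Mean_MAG", "SD_MAG", "Max_MAG"),
    channel = "MAGNITUDE",
    family = "time",
    stat = c("Mean", "SD", "Max")
  )
  cat <- do.call(rbind, rows)
  rownames(cat) <- NULL
  stopifnot(nrow(cat) == 165L, !anyDuplicated(cat$name))
  cat
}

# All statistics for one channel series, as a named vector in catalog order.
channel_feature_block <- function(x, fs) {
  bs <- basic_stats(x)
  cs <- crossing_stats(x, fs)
  ps <- peak_interval_stats(x, fs)
  sp <- tryCatch(spectral_moments(x, fs),
                 hemigait_degenerate_error = function(e) {
                   list(dominant_freq = NaN, centroid = NaN, bandwidth = NaN,
                        skew = NaN, kurt = NaN, entropy = NaN, total_power = 0)
                 })
  pc <- poincare_descriptors(x)
  sdr <- if (pc$sd2 > 0) pc$sd1 / pc$sd2 else if (pc$sd1 == 0) 0 else NaN
  ac <- autocorr_stats(x, fs)
  c(
    Mean = bs$mean, Max = bs$max, Min = bs$min, Range = bs$range,
    SD = bs$sd, Var = bs$var, RMS = bs$rms, TKur = bs$kurtosis,
    TSkew = bs$skewness,
    NZC = as.numeric(cs$n_crossings), MZCI = cs$mean_interval_s,
    SDZCI = cs$sd_interval_s,
    NLM = as.numeric(ps$n_peaks), MZCIL = ps$mean_interval_s,
    SDZCIL = ps$sd_interval_s,
    DF = sp$dominant_freq, CF = sp$centroid, BW = sp$bandwidth,
    Skew = sp$skew, Kur = sp$kurt, SpEnt = sp$entropy, TP = sp$total_power,
    SD1 = pc$sd1, SD2 = pc$sd2, SDR = sdr,
    AC1 = ac$ac1, ACP = ac$first_peak_height
  )
}

#' Extract the feature vector of a recording
#'
#' Computes one value per catalog entry from the (calibrated, walking-segment)
#' recording. The `MAGNITUDE` pseudo-channel is
#' `sqrt(ACC_X^2 + ACC_Y^2 + ACC_Z^2)` per sample. Attributes undefined for
#' the input (zero-variance kurtosis, single-bin spectra, fewer than two
#' crossing/peak intervals, absent autocorrelation peak) are mapped to 0 under
#' the missing-value policy, with one warning naming them, so downstream
#' classifiers always see finite numbers.
#'
#' @param rec an [imu_recording()].
#' @param catalog a catalog as from [feature_catalog()].
#' @return A named numeric vector of `nrow(catalog)` finite values, with
#'   attributes `recording_id` (the recording's subject id).
#' @export
extract_features <- function(rec, catalog = feature_catalog()) {
  validate_imu_recording(rec)
  fs <- rec$sampling_rate_hz
  known <- c(imu_channel_names(), "MAGNITUDE")
  bad <- setdiff(unique(catalog$channel), known)
  if (length(bad)) {
    abort_hg(paste0("catalog references unknown channel(s): ",
                    paste(bad, collapse = ", ")),
             "hemigait_format_error")
  }
  blocks <- lapply(rec$channels, channel_feature_block, fs = fs)
  if ("MAGNITUDE" %in% catalog$channel) {
    mag <- sqrt(rec$channels$ACC_X^2 + rec$channels$ACC_Y^2 + rec$channels$ACC_Z^2)
    blocks$MAGNITUDE <- channel_feature_block(mag, fs)
  }
  vals <- vapply(seq_len(nrow(catalog)), function(i) {
    blocks[[catalog$channel[i]]][[catalog$stat[i]]]
  }, numeric(1))
  names(vals) <- catalog$name
  miss <- !is.finite(vals)
  if (any(miss)) {
    warning(sprintf("missing-value policy: %d attribute(s) undefined, set to 0 (%s)",
                    sum(miss), paste(utils::head(names(vals)[miss], 5L), collapse = ", ")),
            call. = FALSE)
    vals[miss] <- 0
  }
  attr(vals, "recording_id") <- rec$subject_id
  vals
}

#' Extract the feature table of a whole cohort
#'
#' @param cohort a `gait_cohort` from [simulate_cohort()], or a list with
#'   parallel `recordings`, `labels`, `subject_ids`, `recording_ids`.
#' @param catalog a [feature_catalog()].
#' @param calibrate if `TRUE` (default) each recording is passed through
#'   [trim_standby()] and [calibrate_offsets()] first.
#' @param ... passed on to [trim_standby()].
#' @return A [labeled_dataset()] with one row per recording.
#' @export
cohort_features <- function(cohort, catalog = feature_catalog(),
                            calibrate = TRUE, ...) {
  rows <- lapply(seq_along(cohort$recordings), function(i) {
    rec <- cohort$recordings[[i]]
    if (calibrate) {
      seg <- trim_standby(rec, ...)
      rec <- if (!is.null(seg$standby) && duration_s(seg$standby) >= 1) {
        calibrate_offsets(seg$walking, seg$standby)
      } else {
        seg$walking
      }
    }
    suppressWarnings(extract_features(rec, catalog))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- cohort$recording_ids
  labeled_dataset(m, cohort$labels, subject_ids = cohort$subject_ids)
}

#' Write / read a feature table as CSV
#'
#' One row per recording; columns `recording_id`, `label`, then the catalog
#' attribute names.
#'
#' @param data a [labeled_dataset()].
#' @param path CSV path.
#' @return `path` invisibly; `read_feature_table` returns a
#'   [labeled_dataset()].
#' @export
write_feature_table <- function(data, path) {
  df <- data.frame(recording_id = rownames(data$matrix) %||%
                     sprintf("r%03d", seq_len(nrow(data$matrix))),
                   subject_id = data$subject_ids,
                   label = data$labels, check.names = FALSE)
  df <- cbind(df, as.data.frame(data$matrix, check.names = FALSE))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, check.names = FALSE)
  meta <- c("recording_id", "subject_id", "label")
  if (!all(meta %in% names(df))) {
    abort_hg("feature table must have recording_id, subject_id, label columns",
             "hemigait_format_error")
  }
  m <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(m) <- df$recording_id
  labeled_dataset(m, df$label, subject_ids = df$subject_id)
}
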