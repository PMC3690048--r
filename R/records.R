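#' cwtcardio: wavelet-based cardiac alteration and electrodermal stress analysis
#'
#' Analysis stack for single-lead wearable ECG and skin conductance (SCR)
#' recordings: continuous-wavelet R-peak detection, rule-based extrasystole and
#' arrhythmia flagging, heart-rate-variability resampling, per-user gain-ratio
#' stress trees, confusion-matrix diagnostics, and a synthetic signal generator
#' with ground-truth annotations.
#'
#' @keywords internal
"_PACKAGE"

# Device constants for the wearable ECG channel and the SCR front end.
# The ECG channel samples at 250 Hz (4 ms spacing) on a 0-50 mV range with
# 0.013405 mV resolution; the SCR ADC samples at 4 Hz, 0.573 mV steps, 2.35 V
# full scale.
ECG_FS_DEFAULT <- 250
ECG_RESOLUTION_MV <- 0.013405
ECG_RANGE_MV <- c(0, 50)
ECG_SAMPLES_PER_FRAME <- 63L   # 252 ms frame / 4 ms per sample
BREATH_SAMPLES_PER_FRAME <- 18L # 1.008 s frame / 56 ms per sample
BREATH_DT_S <- 0.056
SCR_FS_DEFAULT <- 4
SCR_ADC_STEP_V <- 0.573e-3
SCR_ADC_VMAX_V <- 2.35

#' Construct an ECG record
#'
#' A uniformly sampled single-lead ECG voltage series in millivolts. Time is
#' implicit: sample \code{i} (1-based) occurs at \code{start_time + (i-1)/fs}
#' seconds.
#'
#' @param samples numeric vector of voltages (mV); must be finite.
#' @param fs sampling rate in Hz (> 0); default 250.
#' @param start_time offset of the first sample in seconds.
#' @param subject_id opaque subject label.
#' @param device_grid if \code{TRUE}, samples are declared to lie on the
#'   acquisition grid (integer multiples of 0.013405 mV within 0-50 mV) and
#'   this is validated.
#' @return an object of class \code{ecg_record}.
#' @export
ecg_record <- function(samples, fs = ECG_FS_DEFAULT, start_time = 0,
                       subject_id = NA_character_, device_grid = FALSE) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  if (length(samples) && any(!is.finite(samples)))
    stop("ECG samples must be finite")
  if (isTRUE(device_grid) && length(samples)) {
    k <- samples / ECG_RESOLUTION_MV
    if (max(abs(k - round(k))) * ECG_RESOLUTION_MV > 1e-9)
      stop("device_grid = TRUE but samples are not multiples of ",
           ECG_RESOLUTION_MV, " mV")
    if (min(samples) < ECG_RANGE_MV[1] - 1e-9 ||
        max(samples) > ECG_RANGE_MV[2] + 1e-9)
      stop("device_grid = TRUE but samples exceed the 0-50 mV device range")
  }
  structure(
    list(samples = samples, fs = fs, start_time = as.numeric(start_time),
         subject_id = subject_id, device_grid = isTRUE(device_grid)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$fs, ecg_duration(x),
              if (is.na(x$subject_id)) "" else paste0(", subject ", x$subject_id)))
  invisible(x)
}

#' Sample times and duration of an ECG record
#'
#' @param x an \code{ecg_record}.
#' @return \code{ecg_times()}: vector of sample times (s); \code{ecg_duration()}:
#'   span from first to last sample (s).
#' @export
ecg_times <- function(x) {
  stopifnot(inherits(x, "ecg_record"))
  if (!length(x$samples)) return(numeric(0))
  x$start_time + (seq_along(x$samples) - 1) / x$fs
}

#' @rdname ecg_times
#' @export
ecg_duration <- function(x) {
  stopifnot(inherits(x, "ecg_record"))
  if (length(x$samples) < 2L) return(0)
  (length(x$samples) - 1) / x$fs
}

#' Construct an SCR record
#'
#' A skin-response voltage series (volts) from the resistive divider front end,
#' sampled at 4 Hz by default, optionally carrying per-sample protocol labels.
#'
#' @param samples numeric vector of voltages (V), within the 0-2.35 V ADC range.
#' @param fs sampling rate in Hz (> 0).
#' @param labels optional character vector (same length) with values
#'   \code{"stress"}, \code{"relax"} or \code{"unlabeled"}.
#' @param subject_id opaque subject label.
#' @return an object of class \code{scr_record}.
#' @export
scr_record <- function(samples, fs = SCR_FS_DEFAULT, labels = NULL,
                       subject_id = NA_character_) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (length(samples) && (any(!is.finite(samples)) ||
      min(samples) < -1e-9 || max(samples) > SCR_ADC_VMAX_V + 1e-9))
    stop("SCR samples must be finite and within [0, ", SCR_ADC_VMAX_V, "] V")
  if (is.null(labels)) {
    labels <- rep("unlabeled", length(samples))
  } else {
    labels <- as.character(labels)
    if (length(labels) != length(samples))
      stop("`labels` must match `samples` in length")
    if (!all(labels %in% c("stress", "relax", "unlabeled")))
      stop("labels must be 'stress', 'relax' or 'unlabeled'")
  }
  structure(list(samples = samples, fs = fs, labels = labels,
                 subject_id = subject_id),
            class = "scr_record")
}

#' @export
print.scr_record <- function(x, ...) {
  tab <- table(factor(x$labels, c("stress", "relax", "unlabeled")))
  cat(sprintf("<scr_record> %d samples @ %g Hz (stress %d / relax %d / unlabeled %d)\n",
              length(x$samples), x$fs, tab[["stress"]], tab[["relax"]],
              tab[["unlabeled"]]))
  invisible(x)
}

#' @rdname ecg_times
#' @export
scr_times <- function(x) {
  stopifnot(inherits(x, "scr_record"))
  if (!length(x$samples)) return(numeric(0))
  (seq_along(x$samples) - 1) / x$fs
}

#' Construct an R-peak list
#'
#' Detected beats: occurrence times, normalized detection amplitude in [0, 1]
#' (1 = the strongest deflection in the beat's analysis window) and a class,
#' \code{"R"} or \code{"extrasystole"}.
#'
#' @param times strictly increasing beat times (s).
#' @param norm_amp normalized amplitudes in [0, 1], same length.
#' @param klass character vector of classes, same length.
#' @return an object of class \code{rpeak_list} (also a data.frame).
#' @export
rpeak_list <- function(times = numeric(0),
                       norm_amp = rep(NA_real_, length(times)),
                       klass = rep("R", length(times))) {
  times <- as.numeric(times)
  norm_amp <- as.numeric(norm_amp)
  klass <- as.character(klass)
  if (length(norm_amp) != length(times) || length(klass) != length(times))
    stop("`times`, `norm_amp` and `klass` must have equal length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("beat times must be strictly increasing")
  ok <- is.na(norm_amp) | (norm_amp >= -1e-12 & norm_amp <= 1 + 1e-12)
  if (!all(ok)) stop("norm_amp must lie in [0, 1]")
  if (!all(klass %in% c("R", "extrasystole")))
    stop("klass must be 'R' or 'extrasystole'")
  structure(data.frame(time = times, norm_amp = pmin(pmax(norm_amp, 0), 1),
                       klass = klass, stringsAsFactors = FALSE),
            class = c("rpeak_list", "data.frame"))
}
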