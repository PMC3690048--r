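# Synthetic, annotated ECG and SCR signals with the structure the detectors
# assume, so every stage is testable without recorded data. The ECG template
# is a declared stand-in (piecewise-Gaussian P-QRS-T), not physiologically
# validated morphology; all randomness flows from the single spec seed and the
# caller's RNG state is left untouched.

with_spec_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification for a synthetic ECG recording
#'
#' @param duration_s record length (s).
#' @param fs sampling rate (Hz, default 250).
#' @param hr_bpm nominal heart rate (beats/min, > 0).
#' @param rr_jitter_sd_s SD of Gaussian beat-to-beat interval jitter (s).
#' @param extrasystoles data.frame with columns `beat`, `amp_ratio`,
#'   `prematurity`: beat `beat` becomes a premature, reduced-amplitude beat;
#'   the interval into it is `prematurity` times the nominal RR and the
#'   interval out of it is stretched to a full compensatory pause
#'   (`pause_factor` x nominal RR minus the premature interval). A
#'   `prematurity` below `1/2.2` guarantees the premature-beat timing
#'   inequality fires at that beat.
#' @param arrhythmia_episodes data.frame with columns `beat`, `rr_multiplier`,
#'   `length`: the `length` intervals ending at beats `beat`, `beat + 1`, ...
#'   are multiplied by `rr_multiplier`.
#' @param noise_sd_mV additive white-noise SD (mV).
#' @param baseline_wander numeric `(freq_Hz, amplitude_mV)` sinusoidal wander.
#' @param qrs_amp_mV nominal R-wave amplitude (mV).
#' @param pause_factor compensatory-pause factor (default 2: full
#'   compensation, the premature plus following interval sum to two nominal
#'   RRs).
#' @param seed RNG seed fixing the output exactly.
#' @return object of class `ecg_sim_spec`.
#' @export
ecg_sim_spec <- function(duration_s, fs = ECG_FS_DEFAULT, hr_bpm = 60,
                         rr_jitter_sd_s = 0,
                         extrasystoles = NULL, arrhythmia_episodes = NULL,
                         noise_sd_mV = 0, baseline_wander = c(0, 0),
                         qrs_amp_mV = 1, pause_factor = 2, seed = 1L) {
  if (duration_s <= 0 || fs <= 0 || hr_bpm <= 0 || qrs_amp_mV <= 0)
    stop("duration_s, fs, hr_bpm and qrs_amp_mV must be positive")
  if (rr_jitter_sd_s < 0 || noise_sd_mV < 0)
    stop("noise parameters must be nonnegative")
  if (!is.null(extrasystoles))
    stopifnot(all(c("beat", "amp_ratio", "prematurity") %in% names(extrasystoles)),
              all(extrasystoles$prematurity > 0 & extrasystoles$prematurity < 1))
  if (!is.null(arrhythmia_episodes))
    stopifnot(all(c("beat", "rr_multiplier", "length") %in% names(arrhythmia_episodes)))
  structure(list(duration_s = duration_s, fs = fs, hr_bpm = hr_bpm,
                 rr_jitter_sd_s = rr_jitter_sd_s,
                 extrasystoles = extrasystoles,
                 arrhythmia_episodes = arrhythmia_episodes,
                 noise_sd_mV = noise_sd_mV,
                 baseline_wander = baseline_wander,
                 qrs_amp_mV = qrs_amp_mV, pause_factor = pause_factor,
                 seed = seed), class = "ecg_sim_spec")
}

# Gaussian bump helper; width given as FWHM in seconds.
gauss_wave <- function(t, center, amp, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  amp * exp(-((t - center)^2) / (2 * s^2))
}

#' Generate a synthetic ECG record with ground truth
#'
#' Places template beats (Gaussian P, QRS and T waves of relative amplitudes
#' 0.2 / 1 / 0.3 and widths about 80 / 25 / 120 ms) on an RR schedule built
#' from the nominal heart rate, beat-to-beat jitter, inserted premature beats
#' with compensatory pauses, and RR-multiplier arrhythmia episodes; then adds
#' baseline wander and white noise. Deterministic given `spec$seed`.
#'
#' @param spec an [ecg_sim_spec()].
#' @return list with `ecg` ([ecg_record()]), `truth` ([rpeak_list()] of beat
#'   times and classes with per-beat amplitude ratios in `norm_amp`).
#' @export
gen_ecg <- function(spec) {
  stopifnot(inherits(spec, "ecg_sim_spec"))
  with_spec_seed(spec$seed, {
    rr0 <- 60 / spec$hr_bpm
    n_max <- ceiling(spec$duration_s / rr0) + 8L
    rr <- rr0 + if (spec$rr_jitter_sd_s > 0)
      stats::rnorm(n_max, 0, spec$rr_jitter_sd_s) else numeric(n_max)
    rr <- pmax(rr, 0.25)
    amp_ratio <- rep(1, n_max + 1L)
    klass <- rep("R", n_max + 1L)
    if (!is.null(spec$arrhythmia_episodes)) {
      for (k in seq_len(nrow(spec$arrhythmia_episodes))) {
        ep <- spec$arrhythmia_episodes[k, ]
        idx <- (ep$beat - 1L):(ep$beat - 2L + ep$length)  # intervals into those beats
        idx <- idx[idx >= 1L & idx <= n_max]
        rr[idx] <- rr[idx] * ep$rr_multiplier
      }
    }
    if (!is.null(spec$extrasystoles)) {
      for (k in seq_len(nrow(spec$extrasystoles))) {
        es <- spec$extrasystoles[k, ]
        b <- es$beat
        if (b < 2L || b > n_max) next
        rr[b - 1L] <- es$prematurity * rr0
        rr[b] <- spec$pause_factor * rr0 - rr[b - 1L]
        amp_ratio[b] <- es$amp_ratio
        klass[b] <- "extrasystole"
      }
    }
    t <- cumsum(c(rr0 / 2, rr))
    keep <- t < spec$duration_s - 0.05
    t <- t[keep]; amp_ratio <- amp_ratio[seq_along(t)]
    klass <- klass[seq_along(t)]

    n <- round(spec$duration_s * spec$fs)
    tt <- (seq_len(n) - 1) / spec$fs
    x <- numeric(n)
    for (i in seq_along(t)) {
      a <- spec$qrs_amp_mV * amp_ratio[i]
      lo <- max(1L, floor((t[i] - 0.45) * spec$fs)); hi <- min(n, ceiling((t[i] + 0.55) * spec$fs))
      seg <- lo:hi; ts <- tt[seg]
      x[seg] <- x[seg] +
        gauss_wave(ts, t[i] - 0.16, 0.2 * a, 0.080) +
        gauss_wave(ts, t[i], a, 0.025) +
        gauss_wave(ts, t[i] + 0.25, 0.3 * a, 0.120)
    }
    if (spec$baseline_wander[2] != 0)
      x <- x + spec$baseline_wander[2] *
        sin(2 * pi * spec$baseline_wander[1] * tt)
    if (spec$noise_sd_mV > 0) x <- x + stats::rnorm(n, 0, spec$noise_sd_mV)
    list(ecg = ecg_record(x, fs = spec$fs, subject_id = "synthetic"),
         truth = rpeak_list(t, pmin(amp_ratio, 1), klass))
  })
}

#' Specification for a synthetic SCR recording
#'
#' @param duration_s record length (s).
#' @param fs sampling rate (Hz, default 4).
#' @param baseline_V tonic baseline level (V).
#' @param drift_V_per_min linear tonic drift (V/min).
#' @param responses data.frame with columns `onset_s`, `amplitude_V`,
#'   `rise_s`, `decay_s`: each response rises linearly to its amplitude over
#'   `rise_s` then decays exponentially with time constant `decay_s`.
#' @param noise_sd_V additive white-noise SD (V).
#' @param quantize round to the 0.573 mV ADC step.
#' @param seed RNG seed fixing the output exactly.
#' @return object of class `scr_sim_spec`.
#' @export
scr_sim_spec <- function(duration_s, fs = SCR_FS_DEFAULT, baseline_V = 0.68,
                         drift_V_per_min = 0, responses = NULL,
                         noise_sd_V = 0, quantize = FALSE, seed = 1L) {
  if (duration_s <= 0 || fs <= 0) stop("duration_s and fs must be positive")
  if (!is.null(responses)) {
    stopifnot(all(c("onset_s", "amplitude_V", "rise_s", "decay_s") %in%
                    names(responses)))
    if (any(responses$onset_s < 0 | responses$onset_s >= duration_s))
      stop("response onsets must lie inside the record duration")
  }
  structure(list(duration_s = duration_s, fs = fs, baseline_V = baseline_V,
                 drift_V_per_min = drift_V_per_min, responses = responses,
                 noise_sd_V = noise_sd_V, quantize = isTRUE(quantize),
                 seed = seed), class = "scr_sim_spec")
}

#' Generate a synthetic SCR record with ground-truth labels
#'
#' Baseline plus linear drift plus stimulus-locked response kernels (linear
#' rise, exponential decay) plus white noise, clipped to the ADC range and
#' optionally quantized. Samples during a response span (onset to onset +
#' rise + 3 decay constants) are labeled `"stress"`, the rest `"relax"`.
#'
#' @param spec an [scr_sim_spec()].
#' @return an [scr_record()] with truth labels.
#' @export
gen_scr <- function(spec) {
  stopifnot(inherits(spec, "scr_sim_spec"))
  with_spec_seed(spec$seed, {
    n <- round(spec$duration_s * spec$fs)
    tt <- (seq_len(n) - 1) / spec$fs
    v <- rep(spec$baseline_V, n) + spec$drift_V_per_min * tt / 60
    labels <- rep("relax", n)
    for (i in seq_len(NROW(spec$responses))) {
      rs <- spec$responses[i, ]
      rel <- tt - rs$onset_s
      kern <- ifelse(rel < 0, 0,
              ifelse(rel <= rs$rise_s, rs$amplitude_V * rel / rs$rise_s,
                     rs$amplitude_V * exp(-(rel - rs$rise_s) / rs$decay_s)))
      v <- v + kern
      labels[rel >= 0 & rel <= rs$rise_s + 3 * rs$decay_s] <- "stress"
    }
    if (spec$noise_sd_V > 0) v <- v + stats::rnorm(n, 0, spec$noise_sd_V)
    v <- pmin(pmax(v, 0), SCR_ADC_VMAX_V)
    if (spec$quantize) v <- round(v / SCR_ADC_STEP_V) * SCR_ADC_STEP_V
    scr_record(v, fs = spec$fs, labels = labels, subject_id = "synthetic")
  })
}
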