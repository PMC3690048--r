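# Windowed, normalized R-peak detection on the CWT detection series.
#
# Pipeline per 5 s window: square the selected scale's coefficients, normalize
# the window to max 1, find local maxima separated by a physiological
# refractory period, gate out noise maxima with a crest-factor test, then band
# the surviving candidates by normalized coefficient amplitude: above 60% of
# the beat-level reference -> R wave, 30-60% -> provisional extrasystole.

#' Detect R peaks in an ECG record
#'
#' Computes the Coiflet-5 CWT at a fixed analysis scale, squares the
#' coefficients, and thresholds window-normalized local maxima. Within each
#' window the detection series is normalized to maximum 1; candidate local
#' maxima (refractory-separated, noise-gated) are compared against a beat-level
#' reference amplitude: by default the mean of the candidates' normalized
#' coefficient amplitudes. Candidates above `r_threshold` times the reference
#' are R waves; those in the 30-60% band are provisional extrasystoles, to be
#' confirmed or re-classified downstream by the RR timing rule
#' ([classify_beats()]). Detection times are invariant to positive rescaling
#' of the input.
#'
#' @param ecg an [ecg_record()] at a fixed sampling rate.
#' @param window_s analysis window length in seconds (default 5).
#' @param r_threshold R-wave threshold as a fraction of the reference (0.6).
#' @param es_threshold lower edge of the extrasystole band (0.3).
#' @param wavelet mother wavelet name.
#' @param scale analysis scale in sample units; `NULL` selects it by
#'   detection-energy maximization over [default_scales()].
#' @param reference `"maxima_mean"` (default): reference is the mean normalized
#'   amplitude of the window's candidate maxima; `"window_max"`: reference is
#'   the window maximum (1 after normalization).
#' @param refractory_s minimum separation between accepted candidates (s).
#' @param noise_gate noise rejection strength. A window is processed only if
#'   its maximum exceeds `noise_gate` times its median on the amplitude scale:
#'   Gaussian-noise maxima sit only a few times above the median, QRS-locked
#'   peaks far above it, so windows containing only noise are silenced while
#'   the test stays invariant to rescaling of the input. Within a processed
#'   window, candidates must exceed `min(noise_gate * median, floor_cap)`.
#' @param floor_cap upper cap on the candidate floor as a fraction of the
#'   window maximum (default 0.35): on noisy records the adaptive floor rises
#'   with the noise level, but it never rises into the extrasystole amplitude
#'   band, so low-amplitude premature beats on clean records are never gated.
#' @param window_offset_s shift of the window grid origin (s).
#' @param allow_short if `TRUE`, a record shorter than one window is processed
#'   as a single truncated window instead of raising an error.
#' @return an [rpeak_list()] with classes `"R"` / `"extrasystole"` and
#'   normalized amplitudes relative to the window maximum.
#' @export
detect_r_peaks <- function(ecg, window_s = 5, r_threshold = 0.6,
                           es_threshold = 0.3, wavelet = "coif5",
                           scale = NULL,
                           reference = c("maxima_mean", "window_max"),
                           refractory_s = 0.2, noise_gate = 7,
                           floor_cap = 0.35,
                           window_offset_s = 0, allow_short = FALSE) {
  stopifnot(inherits(ecg, "ecg_record"))
  reference <- match.arg(reference)
  n <- length(ecg$samples)
  dur <- n / ecg$fs
  if (dur < window_s && !allow_short)
    stop("record (", signif(dur, 4), " s) is shorter than one window (",
         window_s, " s); set allow_short = TRUE to process it anyway")
  if (n < 3L) return(rpeak_list())
  if (is.null(scale)) scale <- select_scale(ecg, wavelet)
  series <- transform_coefficients(cwt(ecg, wavelet, scale), scale)

  fs <- ecg$fs
  refractory_n <- max(1L, round(refractory_s * fs))
  # window start indices (1-based), half-open [start, start + window_n)
  window_n <- round(window_s * fs)
  first_start <- 1L + round(window_offset_s * fs) %% window_n - window_n
  starts <- seq(from = first_start, to = n, by = window_n)
  starts <- starts[starts + window_n > 1L]

  # floating-point floor: a constant record leaves only rounding residue in
  # the zero-mean kernel's output; anything this far below the input scale is
  # numerically zero (the bound rescales with the input, keeping detection
  # amplitude-scale invariant)
  eps_floor <- (1e-9 * max(abs(ecg$samples)))^2

  out_t <- numeric(0); out_a <- numeric(0); out_k <- character(0)
  for (s0 in starts) {
    lo <- max(1L, s0); hi <- min(n, s0 + window_n - 1L)
    if (hi - lo + 1L < round(1 * fs) && length(starts) > 1L && s0 == starts[length(starts)])
      next  # final partial window shorter than 1 s is dropped
    w <- series[lo:hi]
    wmax <- max(w)
    if (wmax <= eps_floor) next
    wn <- w / wmax
    ampn <- sqrt(wn)  # amplitude (coefficient) scale, window max = 1
    # window-level noise rejection: in pure noise even the upper tail of the
    # amplitude series sits only a few times above the median (and the 99.9th
    # percentile is robust against a single spike), while QRS-bearing windows
    # tower over it
    amed <- stats::median(ampn)
    a999 <- stats::quantile(ampn, 0.999, names = FALSE)
    if (a999 <= noise_gate * amed) next
    cand <- local_maxima(wn)
    cand <- cand[ampn[cand] > min(noise_gate * amed, floor_cap)]
    if (!length(cand)) next
    # refractory: greedy keep-largest within refractory_n samples
    cand <- cand[order(wn[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (ci in cand)
      if (!length(kept) || min(abs(kept - ci)) >= refractory_n)
        kept <- c(kept, ci)
    kept <- sort(kept)
    amp <- ampn[kept]
    ref <- if (reference == "maxima_mean") mean(amp) else 1
    klass <- ifelse(amp > r_threshold * ref, "R",
             ifelse(amp > es_threshold * ref, "extrasystole", NA))
    sel <- !is.na(klass)
    out_t <- c(out_t, ecg$start_time + (lo + kept[sel] - 2L) / fs)
    out_a <- c(out_a, amp[sel])
    out_k <- c(out_k, klass[sel])
  }
  if (length(out_t) > 1L) {
    ord <- order(out_t)
    out_t <- out_t[ord]; out_a <- out_a[ord]; out_k <- out_k[ord]
    # refractory across window boundaries: a QRS straddling a boundary can
    # fire in both adjacent windows; keep the larger of any pair closer than
    # the refractory period
    repeat {
      close <- which(diff(out_t) < refractory_s)
      if (!length(close)) break
      i <- close[1]
      drop <- if (out_a[i] >= out_a[i + 1L]) i + 1L else i
      out_t <- out_t[-drop]; out_a <- out_a[-drop]; out_k <- out_k[-drop]
    }
  }
  rpeak_list(out_t, out_a, out_k)
}

# Indices of strict interior local maxima (plateau-safe: first sample of a
# plateau that subsequently falls).
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}
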