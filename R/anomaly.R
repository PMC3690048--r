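# Rule-based beat classification and arrhythmia flagging on RR intervals.
#
# Two printed ratio rules operate on the beat times t(i):
#   extrasystole (timing): [t(i) - t(i-1)] * 2.2 < [t(i+1) - t(i)]
#   arrhythmia (lengthening): RR(i) >= 1.3 * RR(i-1)
#   arrhythmia (shortening): 1.3 * RR(i) <= RR(i-1)
# Both are pure ratio rules: invariant to time shift and covariant under
# positive time scaling.

#' Premature-beat timing rule at one beat
#'
#' Returns `TRUE` iff the interval into beat `i` is so short relative to the
#' interval out of it that the beat is premature and followed by a
#' compensatory pause: `(t[i] - t[i-1]) * factor < (t[i+1] - t[i])` (strict).
#'
#' @param t strictly increasing beat times (s).
#' @param i interior beat index, `2 <= i <= length(t) - 1`.
#' @param factor timing factor (default 2.2).
#' @return logical scalar.
#' @export
extrasystole_timing_rule <- function(t, i, factor = 2.2) {
  n <- length(t)
  if (n > 1L && any(diff(t) <= 0)) stop("beat times must be strictly increasing")
  if (i < 2L || i > n - 1L)
    stop("index i = ", i, " has no two neighbours (n = ", n, ")")
  (t[i] - t[i - 1L]) * factor < (t[i + 1L] - t[i])
}

#' Classify detected beats into R waves and extrasystoles
#'
#' Combines the amplitude band with the timing rule: beats whose normalized
#' amplitude lies in the 30-60% band are extrasystoles; beats above 60% whose
#' surrounding intervals satisfy the timing inequality are re-classified as
#' extrasystoles despite their amplitude; all other beats are R. The first and
#' last beats cannot be tested by the timing rule and keep their amplitude
#' class.
#'
#' @param peaks an [rpeak_list()] (classes as provisionally banded by the
#'   detector, or all `"R"` when amplitudes are absent).
#' @param factor timing factor (default 2.2).
#' @return object of class `anomaly_report`: list with `peaks` (re-classified
#'   [rpeak_list()]), `extrasystole_indices`, `arrhythmia_indices`,
#'   `episodes` (data.frame of merged contiguous arrhythmia spans), `rr`
#'   (data.frame `anchor_t`, `rr`).
#' @export
classify_beats <- function(peaks, factor = 2.2) {
  stopifnot(inherits(peaks, "rpeak_list"))
  n <- nrow(peaks)
  klass <- peaks$klass
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (klass[i] == "R" &&
          extrasystole_timing_rule(peaks$time, i, factor))
        klass[i] <- "extrasystole"
    }
  }
  arr <- detect_arrhythmia(peaks$time)
  rr <- rr_from_beats(peaks$time)
  structure(list(
    peaks = rpeak_list(peaks$time, peaks$norm_amp, klass),
    extrasystole_indices = which(klass == "extrasystole"),
    arrhythmia_indices = arr,
    episodes = arrhythmia_episodes(arr, peaks$time),
    rr = rr), class = "anomaly_report")
}

#' @export
print.anomaly_report <- function(x, ...) {
  cat(sprintf("<anomaly_report> %d beats: %d extrasystole(s), %d arrhythmic interval(s), %d episode(s)\n",
              nrow(x$peaks), length(x$extrasystole_indices),
              length(x$arrhythmia_indices), nrow(x$episodes)))
  invisible(x)
}

#' Flag arrhythmic RR transitions
#'
#' Beat index `i` (3-based onward) is flagged iff the interval ending at it
#' lengthens or shortens by 30% or more relative to its predecessor:
#' `RR(i) >= ratio * RR(i-1)` or `ratio * RR(i) <= RR(i-1)`, with
#' `RR(i) = t(i) - t(i-1)`. Both comparisons are inclusive. Fewer than three
#' beats yield no flags.
#'
#' @param t strictly increasing beat times (s).
#' @param ratio arrhythmia ratio (default 1.3).
#' @return integer vector of flagged beat indices (interval end-indices).
#' @export
detect_arrhythmia <- function(t, ratio = 1.3) {
  n <- length(t)
  if (n > 1L && any(diff(t) <= 0)) stop("beat times must be strictly increasing")
  if (n < 3L) return(integer(0))
  rr <- diff(t)                     # rr[j] = t(j+1) - t(j), interval ending at beat j+1
  cur <- rr[-1L]; prev <- rr[-length(rr)]
  flagged <- which(cur >= ratio * prev | ratio * cur <= prev) + 2L
  as.integer(flagged)
}

# Merge contiguous flagged interval end-indices into episode spans
# (merge gap = 0 beats).
arrhythmia_episodes <- function(indices, t) {
  if (!length(indices))
    return(data.frame(start_index = integer(0), end_index = integer(0),
                      start_t = numeric(0), end_t = numeric(0)))
  breaks <- c(0L, which(diff(indices) > 1L), length(indices))
  spans <- lapply(seq_len(length(breaks) - 1L), function(k) {
    idx <- indices[(breaks[k] + 1L):breaks[k + 1L]]
    data.frame(start_index = idx[1L] - 1L, end_index = idx[length(idx)],
               start_t = t[idx[1L] - 1L], end_t = t[idx[length(idx)]])
  })
  do.call(rbind, spans)
}
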