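# Heart-rate variability: RR series construction, shape-preserving cubic
# Hermite resampling, and windowed mean/SD statistics.

#' Build an RR-interval series from beat times
#'
#' Each interval is anchored at its end beat: `anchor_t[i] = t[i+1]`,
#' `rr[i] = t[i+1] - t[i]`. The intervals sum exactly to the beat-train span.
#'
#' @param t strictly increasing beat times (s); fewer than two beats give an
#'   empty series.
#' @return object of class `rr_series`: data.frame with `anchor_t`, `rr`.
#' @export
rr_from_beats <- function(t) {
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("beat times must be strictly increasing")
  if (length(t) < 2L)
    return(structure(data.frame(anchor_t = numeric(0), rr = numeric(0)),
                     class = c("rr_series", "data.frame")))
  structure(data.frame(anchor_t = t[-1L], rr = diff(t)),
            class = c("rr_series", "data.frame"))
}

#' Resample an RR series uniformly by cubic Hermite interpolation
#'
#' Uses the shape-preserving piecewise cubic Hermite interpolant (pchip, with
#' derivative limiting at the knots and zero slope at data extrema): it passes
#' through every knot exactly and never overshoots the local data range, so a
#' monotone run of RR values maps to a monotone curve. Sampled uniformly at
#' `out_fs` on `[min(anchor_t), max(anchor_t)]`. `hrv_interpolant()` returns
#' the interpolant as a function for evaluation at arbitrary times.
#'
#' @param series an [rr_from_beats()] result with at least 2 intervals.
#' @param out_fs output sampling rate in Hz (default 4, matching the SCR rate
#'   for joint plots).
#' @return data.frame with `t` (s) and `rr` (s).
#' @export
interpolate_hrv <- function(series, out_fs = 4) {
  f <- hrv_interpolant(series)
  if (!is.numeric(out_fs) || out_fs <= 0) stop("out_fs must be positive")
  t0 <- series$anchor_t[1L]; t1 <- series$anchor_t[nrow(series)]
  tt <- seq(t0, t1, by = 1 / out_fs)
  if (tt[length(tt)] < t1) tt <- c(tt, t1)
  data.frame(t = tt, rr = f(tt))
}

#' @rdname interpolate_hrv
#' @export
hrv_interpolant <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  if (nrow(series) < 2L)
    stop("at least 2 RR intervals are required for interpolation")
  x <- series$anchor_t; y <- series$rr
  function(t) pracma::pchip(x, y, t)
}

#' Windowed RR statistics
#'
#' Sample mean and sample standard deviation (n-1 denominator) of the raw RR
#' intervals whose anchor times fall inside the window. Window bounds may be
#' given in either order. With `unit = "bpm"` the statistics are computed on
#' instantaneous heart rate `60/rr` instead.
#'
#' @param series an [rr_from_beats()] result.
#' @param window numeric length-2 `(start_s, end_s)` (closed interval).
#' @param unit `"s"` (RR seconds, default) or `"bpm"`.
#' @return named numeric vector `c(mean =, sd =, n =)`.
#' @export
rr_stats <- function(series, window = range(series$anchor_t), unit = c("s", "bpm")) {
  stopifnot(inherits(series, "rr_series"))
  unit <- match.arg(unit)
  window <- sort(as.numeric(window))
  sel <- series$anchor_t >= window[1] & series$anchor_t <= window[2]
  if (!any(sel))
    stop("no RR intervals fall inside the window [",
         window[1], ", ", window[2], "]")
  v <- series$rr[sel]
  if (unit == "bpm") v <- 60 / v
  c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0, n = length(v))
}
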