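# Continuous wavelet transform with the Coiflet-5 mother wavelet.
#
# The wavelet function is built at load time from the published 30-tap
# orthonormal reconstruction filter via the two-scale (cascade) refinement
#   phi(x) = sqrt(2) * sum_n h[n] phi(2x - n),  psi(x) = sqrt(2) * sum_n g[n]
#   phi(2x - n),  g[k] = (-1)^k h[N-1-k],
# iterated to fixed point on a dyadic grid over the support [0, N-1].

# Coiflet-5 orthonormal reconstruction low-pass filter (sums to sqrt(2)).
COIF5_REC_LO <- c(
  -2.1208186206749400e-04,  3.5857774116175768e-04,
   2.1782943778456947e-03, -4.1593126275786402e-03,
  -1.0131584846900276e-02,  2.3408322118927783e-02,
   2.8169744270532353e-02, -9.1921588060086087e-02,
  -5.2046670253554764e-02,  4.2157126673075435e-01,
   7.7429362286032744e-01,  4.3798230665916338e-01,
  -6.2037751574981960e-02, -1.0556315130733723e-01,
   4.1287530472117834e-02,  3.2674799467057355e-02,
  -1.9758391600965465e-02, -9.1595073386761625e-03,
   6.7615202206204169e-03,  2.4315754425382886e-03,
  -1.6616273039298788e-03, -6.3755892612588115e-04,
   3.0185794166824478e-04,  1.4035632812373243e-04,
  -4.1219861924265501e-05, -2.1270221672515614e-05,
   3.7007277113394796e-06,  2.0612203985788783e-06,
  -1.6237995172048338e-07, -9.6040101127678941e-08)

SUPPORTED_WAVELETS <- c("coif5")

.wavelet_cache <- new.env(parent = emptyenv())

# Fixed-point cascade on a dyadic grid; returns list(x, phi, psi).
cascade_wavelet <- function(h = COIF5_REC_LO, level = 10L, iter = 40L) {
  n_taps <- length(h)
  g <- (-1)^(seq_len(n_taps) - 1) * rev(h)  # quadrature mirror filter
  step <- 2^-level
  x <- seq(0, n_taps - 1, by = step)
  phi <- as.numeric(x >= 0 & x < 1)  # Haar-like seed
  refine <- function(p, filt) {
    acc <- numeric(length(x))
    for (k in seq_len(n_taps)) {
      acc <- acc + filt[k] *
        stats::approx(x, p, xout = 2 * x - (k - 1), yleft = 0, yright = 0,
                      rule = 2, ties = "ordered")$y
    }
    sqrt(2) * acc
  }
  for (i in seq_len(iter)) phi <- refine(phi, h)
  psi <- refine(phi, g)
  list(x = x, phi = phi, psi = psi)
}

#' The Coiflet-5 scaling and wavelet functions
#'
#' Tabulated on a dyadic grid over the support \eqn{[0, 29]}; computed once per
#' session by cascade refinement of the orthonormal filter and cached.
#'
#' @param wavelet wavelet name; only `"coif5"` is supported.
#' @return list with `x` (grid), `phi`, `psi`, and `center` (abscissa of the
#'   dominant extremum of `psi`, used to align detection peaks with the R apex).
#' @export
wavelet_function <- function(wavelet = "coif5") {
  if (!wavelet %in% SUPPORTED_WAVELETS)
    stop("unsupported wavelet '", wavelet, "'; supported: ",
         paste(SUPPORTED_WAVELETS, collapse = ", "))
  if (is.null(.wavelet_cache[[wavelet]])) {
    wf <- cascade_wavelet()
    wf$center <- wf$x[which.max(abs(wf$psi))]
    # cumulative integral of psi, used to integrate the kernel over sample
    # cells (accurate at small scales where point-sampling would alias)
    step <- wf$x[2] - wf$x[1]
    wf$psi_cum <- c(0, cumsum((wf$psi[-1] + wf$psi[-length(wf$psi)]) / 2) * step)
    .wavelet_cache[[wavelet]] <- wf
  }
  .wavelet_cache[[wavelet]]
}

# Analysis kernel at scale `a` (in samples): the L2-normalized wavelet
# integrated over each unit sample cell, w_d = sqrt(a) * [Psi(u_hi) -
# Psi(u_lo)] with u = d/a + center and Psi the cumulative integral of psi.
# Treating the signal as piecewise constant per sample, sum(x[b+d] * w_d)
# evaluates the CWT integral exactly up to the tabulation step; the kernel is
# exactly zero-mean, so constant offsets never leak into coefficients.
cwt_kernel <- function(a, wavelet = "coif5") {
  wf <- wavelet_function(wavelet)
  dmin <- ceiling(-wf$center * a - 0.5)
  dmax <- floor((max(wf$x) - wf$center) * a + 0.5)
  d <- dmin:dmax
  edges <- (c(d[1] - 0.5, d + 0.5)) / a + wf$center
  Psi <- stats::approx(wf$x, wf$psi_cum, xout = edges,
                       yleft = 0, yright = wf$psi_cum[length(wf$psi_cum)],
                       ties = "ordered")$y
  list(d = d, w = sqrt(a) * diff(Psi))
}

#' Continuous wavelet transform of an ECG record
#'
#' Computes \eqn{C(a,b) = a^{-1/2} \sum_t x(t)\, \psi((t-b)/a)} on the sample
#' grid \eqn{b} for each scale \eqn{a} (scales in sample units). Beyond the
#' record the signal is extended by reflection, which avoids the spurious
#' edge response a zero extension would create at the record boundaries. The
#' real Coiflet-5 wavelet makes conjugation a no-op. The transform is linear
#' in the signal and maps the zero signal to zero coefficients.
#'
#' @param ecg an [ecg_record()].
#' @param wavelet mother wavelet name (default `"coif5"`).
#' @param scales positive scales in sample units.
#' @return object of class `cwt_coefficients`: list with `a` (scales), `b`
#'   (0-based sample shifts), matrix `C` (scales x samples), `wavelet`, `fs`.
#' @export
cwt <- function(ecg, wavelet = "coif5", scales = default_scales(ecg$fs)) {
  stopifnot(inherits(ecg, "ecg_record"))
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("scales must be positive and finite")
  x <- ecg$samples
  n <- length(x)
  C <- matrix(0, nrow = length(scales), ncol = n)
  if (n > 0) {
    for (si in seq_along(scales)) {
      k <- cwt_kernel(scales[si], wavelet)
      m <- length(k$w)
      # reflect the record at both ends over the kernel support
      p <- min(m, n - 1L)
      xp <- if (p > 0L) c(x[(p + 1L):2L], x, x[(n - 1L):(n - p)]) else x
      z <- stats::convolve(xp, k$w, type = "open")  # z[t] = sum_l xp[t-m+l] w[l]
      idx <- seq_len(n) + p + k$d[1] + m - 1L
      keep <- idx >= 1L & idx <= length(xp) + m - 1L
      row <- numeric(n)
      row[keep] <- z[idx[keep]]
      C[si, ] <- row
    }
  }
  structure(list(a = scales, b = seq_len(n) - 1L, C = C,
                 wavelet = wavelet, fs = ecg$fs),
            class = "cwt_coefficients")
}

#' @export
print.cwt_coefficients <- function(x, ...) {
  cat(sprintf("<cwt_coefficients> %s, %d scale(s) x %d shifts @ %g Hz\n",
              x$wavelet, length(x$a), ncol(x$C), x$fs))
  invisible(x)
}

#' Turn CWT coefficients into a detection series
#'
#' Selects one scale's coefficient row and sharpens it into a nonnegative
#' per-sample detection series. The default strategy squares the coefficients,
#' which makes the series invariant to the overall sign of the ECG and
#' sharpens QRS-locked peaks; `"abs"` takes magnitudes instead.
#'
#' @param coeffs a [cwt()] result.
#' @param scale_select one of the computed scales.
#' @param strategy `"square"` (default) or `"abs"`.
#' @return numeric detection series aligned to the sample grid.
#' @export
transform_coefficients <- function(coeffs, scale_select,
                                   strategy = c("square", "abs")) {
  stopifnot(inherits(coeffs, "cwt_coefficients"))
  strategy <- match.arg(strategy)
  si <- which(abs(coeffs$a - scale_select) < 1e-12)
  if (length(si) != 1L)
    stop("scale ", scale_select, " was not computed; available: ",
         paste(signif(coeffs$a, 6), collapse = ", "))
  row <- coeffs$C[si, ]
  if (strategy == "square") row^2 else abs(row)
}

#' Default analysis scales and automatic scale selection
#'
#' The scale grid spans wavelet main-lobe durations matched to QRS widths
#' (roughly 20-120 ms at 250 Hz). `select_scale()` fixes the analysis scale by
#' a matched-filter criterion on the squared-coefficient detection series:
#' among scales whose peak response reaches at least `min_response` of the
#' grid's best (the many-vanishing-moments wavelet annihilates smooth QRS
#' shapes at very small scales, leaving a degenerate residue that must be
#' excluded), it maximizes the peak-to-RMS ratio `max(s)/sqrt(mean(s^2))`.
#' Raw series energy would favour the broad, high-amplitude T-wave scales
#' instead of the QRS-matched one.
#'
#' @param fs sampling rate (Hz).
#' @return `default_scales()`: numeric scale grid (sample units).
#' @export
default_scales <- function(fs = ECG_FS_DEFAULT) {
  # main lobe of coif5 spans ~3 abscissa units -> a = width_s * fs / 3
  widths_ms <- c(20, 30, 40, 60, 80, 100, 120)
  widths_ms / 1000 * fs / 3
}

#' @rdname default_scales
#' @param ecg an [ecg_record()].
#' @param wavelet mother wavelet name.
#' @param scales candidate scales.
#' @param min_response minimum peak response relative to the grid's best.
#' @return `select_scale()`: the selected scale (scalar).
#' @export
select_scale <- function(ecg, wavelet = "coif5",
                         scales = default_scales(ecg$fs),
                         min_response = 0.01) {
  coeffs <- cwt(ecg, wavelet, scales)
  series <- lapply(scales, function(a) transform_coefficients(coeffs, a))
  peak <- vapply(series, max, numeric(1))
  snr <- vapply(series, function(s) {
    rms <- sqrt(mean(s^2))
    if (rms <= 0) -Inf else max(s) / rms
  }, numeric(1))
  ok <- peak >= min_response * max(peak)
  scales[ok][which.max(snr[ok])]
}
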