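# Shared fixtures built in code.

clean_ecg <- function(duration_s = 60, hr_bpm = 75, seed = 3, ...) {
  gen_ecg(ecg_sim_spec(duration_s, hr_bpm = hr_bpm, seed = seed, ...))
}

# Two-Gaussian SCR sample: stress shifted +delta_V over relax baseline.
two_gaussian_scr <- function(n_per_class = 200, relax_V = 0.68, delta_V = 0.05,
                             sd_V = 0.015, seed = 42) {
  set.seed(seed)
  v <- c(rnorm(n_per_class, relax_V + delta_V, sd_V),
         rnorm(n_per_class, relax_V, sd_V))
  scr_record(pmin(pmax(v, 0), 2.35), fs = 4,
             labels = rep(c("stress", "relax"), each = n_per_class))
}

# Literal per-index re-evaluation of the printed timing/arrhythmia rules,
# used as the brute-force oracle against the vectorized implementations.
oracle_extrasystole <- function(t, factor = 2.2) {
  out <- logical(length(t))
  for (i in seq_along(t)) {
    if (i >= 2 && i <= length(t) - 1)
      out[i] <- (t[i] - t[i - 1]) * factor < (t[i + 1] - t[i])
  }
  which(out)
}

oracle_arrhythmia <- function(t, ratio = 1.3) {
  out <- integer(0)
  for (i in seq_along(t)) {
    if (i >= 3) {
      rr_i <- t[i] - t[i - 1]
      rr_p <- t[i - 1] - t[i - 2]
      if (rr_i >= ratio * rr_p || ratio * rr_i <= rr_p) out <- c(out, i)
    }
  }
  out
}

# Exhaustive maximum-cardinality matching of truth/detected within tolerance.
oracle_max_matching <- function(truth, detected, tol) {
  if (!length(truth) || !length(detected)) return(0L)
  best <- oracle_max_matching(truth[-1], detected, tol)
  for (j in seq_along(detected)) {
    if (abs(detected[j] - truth[1]) <= tol) {
      best <- max(best, 1L + oracle_max_matching(truth[-1], detected[-j], tol))
    }
  }
  best
}
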