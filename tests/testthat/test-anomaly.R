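# Ratio rules for premature beats and arrhythmic RR transitions.

test_that("the premature-beat timing inequality follows its printed form", {
  expect_true(extrasystole_timing_rule(c(0, 0.4, 1.5), 2))   # 0.88 < 1.1
  expect_false(extrasystole_timing_rule(c(0, 0.8, 1.6), 2))  # 1.76 < 0.8 fails
  t <- seq(0, 10, by = 1)  # regular 60 bpm train
  for (i in 2:(length(t) - 1)) expect_false(extrasystole_timing_rule(t, i))
  expect_error(extrasystole_timing_rule(c(0, 1, 2), 1), "neighbours")
  expect_error(extrasystole_timing_rule(c(0, 1, 2), 3), "neighbours")
})

test_that("arrhythmia flags follow the two inclusive ratio inequalities", {
  # RR (0.8, 0.8, 1.1): lengthening at the 4th beat (1.1 >= 1.04)
  expect_identical(detect_arrhythmia(cumsum(c(0, 0.8, 0.8, 1.1))), 4L)
  # RR (1.04, 0.8): shortening boundary 0.8 * 1.3 = 1.04 <= 1.04 is inclusive
  expect_identical(detect_arrhythmia(cumsum(c(0, 1.04, 0.8))), 3L)
  # one interval stretched 1.5x in a regular train: flags entering and leaving
  rr <- rep(0.8, 10); rr[5] <- 1.2
  flags <- detect_arrhythmia(cumsum(c(0, rr)))
  expect_identical(flags, c(6L, 7L))
  expect_identical(detect_arrhythmia(c(0, 1)), integer(0))
})

test_that("vectorized rules match literal per-index oracles on random trains", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(3:50, 1)
    t <- cumsum(c(0, runif(n - 1, 0.3, 1.6)))
    expect_identical(detect_arrhythmia(t), oracle_arrhythmia(t))
    vec <- which(vapply(seq_along(t), function(i)
      i >= 2 && i <= n - 1 && extrasystole_timing_rule(t, i), logical(1)))
    expect_identical(vec, oracle_extrasystole(t))
  }
})

test_that("classifications are invariant to time shift and positive time scaling", {
  set.seed(7)
  t <- cumsum(c(0, runif(30, 0.3, 1.6)))
  base_arr <- detect_arrhythmia(t)
  base_es <- oracle_extrasystole(t)
  for (f in list(function(x) x + 137, function(x) x * 3.7,
                 function(x) x * 0.21 + 5)) {
    expect_identical(detect_arrhythmia(f(t)), base_arr)
    expect_identical(oracle_extrasystole(f(t)), base_es)
  }
})

test_that("regular trains carry no anomalies and degenerate input is quiet", {
  t <- seq(0.5, 59.5, by = 0.75)
  rep0 <- classify_beats(rpeak_list(t, rep(0.95, length(t)),
                                    rep("R", length(t))))
  expect_length(rep0$extrasystole_indices, 0)
  expect_length(rep0$arrhythmia_indices, 0)
  empty <- classify_beats(rpeak_list())
  expect_length(empty$extrasystole_indices, 0)
  expect_equal(nrow(empty$rr), 0)
})

test_that("amplitude band and timing rule combine as documented", {
  # a 0.45-amplitude beat among 0.9 beats is flagged by the band alone
  t <- seq(0.5, 8.5, by = 1)
  amp <- rep(0.9, length(t)); amp[4] <- 0.45
  kl <- ifelse(amp <= 0.6, "extrasystole", "R")
  rep1 <- classify_beats(rpeak_list(t, amp, kl))
  expect_identical(rep1$extrasystole_indices, 4L)

  # a high-amplitude beat whose intervals satisfy the x2.2 rule is re-classified
  t2 <- c(0, 0.8, 1.6, 1.9, 3.2, 4.0, 4.8)  # beat 4 premature, long pause after
  rep2 <- classify_beats(rpeak_list(t2, rep(0.9, 7), rep("R", 7)))
  expect_true(4L %in% rep2$extrasystole_indices)
  expect_length(rep2$extrasystole_indices, 1)
})

test_that("contiguous arrhythmia flags merge into episode spans", {
  rr <- rep(0.8, 12); rr[6] <- 1.2; rr[7] <- 1.7
  t <- cumsum(c(0, rr))
  rep1 <- classify_beats(rpeak_list(t, rep(0.9, length(t)), rep("R", length(t))))
  expect_gt(nrow(rep1$episodes), 0)
  expect_true(all(rep1$episodes$end_index >= rep1$episodes$start_index))
  # flags inside one episode are contiguous
  for (k in seq_len(nrow(rep1$episodes))) {
    span <- rep1$episodes[k, ]
    inside <- rep1$arrhythmia_indices[
      rep1$arrhythmia_indices >= span$start_index + 1 &
      rep1$arrhythmia_indices <= span$end_index]
    expect_identical(inside, seq(min(inside), max(inside)))
  }
})
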