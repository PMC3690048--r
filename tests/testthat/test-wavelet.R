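# Coiflet-5 construction and CWT properties.

test_that("cascade reproduces independent reference values of phi and psi", {
  # reference values computed once with an independent wavelet library from
  # the same published 30-tap filter (dyadic cascade, level 10)
  wf <- wavelet_function("coif5")
  at <- function(x0, v) v[which.min(abs(wf$x - x0))]
  # the fixed point of the grid refinement differs from the reference's
  # finite dyadic construction by O(1e-3) absolute; compare absolutely
  expect_lt(abs(at(10, wf$phi) - 1.100438041300906), 2e-3)
  expect_lt(abs(at(10, wf$psi) - 0.003365742604965841), 2e-3)
  expect_lt(abs(at(13, wf$psi) - -0.12135442000506322), 2e-3)
  i <- which.max(abs(wf$psi))
  expect_lt(abs(wf$x[i] - 14.4970703125), 2e-2)
  expect_lt(abs(wf$psi[i] - -1.2948115358163317), 2e-3)
  # orthonormal wavelet: unit L2 norm, zero mean
  step <- wf$x[2] - wf$x[1]
  expect_equal(sum(wf$psi^2) * step, 1, tolerance = 1e-3)
  expect_equal(sum(wf$psi) * step, 0, tolerance = 1e-6)
})

test_that("unsupported wavelet names are rejected with the supported list", {
  rec <- ecg_record(rnorm(100), 250)
  expect_error(cwt(rec, wavelet = "db4"), "coif5")
})

test_that("cwt of the zero signal is zero and the transform is linear", {
  z <- ecg_record(rep(0, 500), 250)
  co <- cwt(z, scales = c(2, 5))
  expect_true(all(co$C == 0))

  set.seed(1)
  x <- rnorm(500)
  c1 <- cwt(ecg_record(x, 250), scales = c(2, 5))$C
  c2 <- cwt(ecg_record(2 * x, 250), scales = c(2, 5))$C
  expect_equal(c2, 2 * c1, tolerance = 1e-9)
  y <- rnorm(500)
  cxy <- cwt(ecg_record(x + y, 250), scales = 5)$C
  cy <- cwt(ecg_record(y, 250), scales = 5)$C
  expect_equal(cxy, c1[2, , drop = FALSE] + cy, tolerance = 1e-9)
})

test_that("impulse response equals a direct fine-grid evaluation of the CWT integral", {
  # unit impulse in the middle of the record; the oracle evaluates
  # C(a,b) = a^(-1/2) * integral of psi over the impulse's sample cell by
  # fine-grid Riemann summation on the tabulated wavelet, independently of
  # the convolution path
  n <- 401L
  t0 <- 201L
  x <- numeric(n); x[t0] <- 1
  rec <- ecg_record(x, 250)
  wf <- wavelet_function("coif5")
  for (a in c(2, 4, 7.5)) {
    co <- cwt(rec, scales = a)
    b_probe <- t0 + seq(-25L, 25L, by = 5L)
    oracle <- vapply(b_probe, function(b) {
      h <- 2^-10 * a
      tt <- seq((t0 - b) - 0.5, (t0 - b) + 0.5, by = h / a)
      u <- tt / a + wf$center
      psi_u <- stats::approx(wf$x, wf$psi, xout = u, yleft = 0, yright = 0,
                             ties = "ordered")$y
      sum(psi_u) * (h / a) / sqrt(a)
    }, numeric(1))
    # compare against the strongest coefficient: elementwise relative error
    # is meaningless at the wavelet's near-zero tails
    expect_lt(max(abs(co$C[1, b_probe] - oracle)), 1e-3 * max(abs(oracle)))
  }
})

test_that("detection series is sign-invariant, nonnegative and zero on zero input", {
  sim <- clean_ecg(20)
  co <- cwt(sim$ecg, scales = 5)
  s <- transform_coefficients(co, 5)
  expect_true(all(s >= 0))
  neg <- cwt(ecg_record(-sim$ecg$samples, 250), scales = 5)
  expect_equal(transform_coefficients(neg, 5), s, tolerance = 1e-12)
  z <- cwt(ecg_record(rep(0, 1000), 250), scales = 5)
  expect_true(all(transform_coefficients(z, 5) == 0))
  expect_error(transform_coefficients(co, 99), "not computed")
})

test_that("scale selection lands on a QRS-matched scale for clean and noisy records", {
  sel_clean <- select_scale(clean_ecg(30)$ecg)
  expect_gte(sel_clean, 2)
  expect_lte(sel_clean, 7)
  sel_noisy <- select_scale(clean_ecg(30, noise_sd_mV = 0.05, seed = 8)$ecg)
  expect_gte(sel_noisy, 2)
  expect_lte(sel_noisy, 7)
})
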