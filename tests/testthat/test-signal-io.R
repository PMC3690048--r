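# CSV/TSV round trips and frame reassembly.

test_that("ECG CSV round-trips bit-identically, with and without time column", {
  sim <- clean_ecg(10, hr_bpm = 60, noise_sd_mV = 0.02, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ecg_csv(sim$ecg, f)
  back <- read_ecg_csv(f, fs = 250)
  expect_identical(back$samples, sim$ecg$samples)
  expect_equal(length(back$samples), 2500L)
  expect_equal(ecg_duration(back), 9.996)

  write_ecg_csv(sim$ecg, f, times = TRUE)
  back2 <- read_ecg_csv(f, fs = 250)
  expect_identical(back2$samples, sim$ecg$samples)

  zeros <- ecg_record(rep(0, 10), 250)
  write_ecg_csv(zeros, f)
  b3 <- read_ecg_csv(f, 250)
  expect_equal(length(b3$samples), 10L)
  expect_equal(ecg_duration(b3), 0.036)
})

test_that("malformed ECG CSV input raises informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.1", "0.2", "abc", "0.3"), f)
  expect_error(read_ecg_csv(f, 250), "line 3")
  writeLines(c("0.0,0.1", "0.004,0.2", "0.012,0.3"), f)  # gap in timestamps
  expect_error(read_ecg_csv(f, 250), "not uniform")
  expect_error(read_ecg_csv(tempfile(), 250), "not found")
})

test_that("device-grid validation accepts grid multiples and rejects others", {
  ok <- ecg_record(c(0, 1, 3, 1000) * 0.013405, 250, device_grid = TRUE)
  expect_true(ok$device_grid)
  expect_error(ecg_record(c(0.01), 250, device_grid = TRUE), "multiples")
  expect_error(ecg_record(0.013405 * 4000, 250, device_grid = TRUE), "range")
})

test_that("SCR CSV round-trips samples and labels", {
  rec <- scr_record(c(0.68, 0.7, 0.71), 4, labels = c("relax", "stress", "stress"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_scr_csv(rec, f)
  back <- read_scr_csv(f)
  expect_identical(back$samples, rec$samples)
  expect_identical(back$labels, rec$labels)
  expect_error(scr_record(c(3), 4), "within")
})

test_that("annotation TSV round-trips and enforces sorted input", {
  pk <- rpeak_list(c(0.5, 1.2, 2.0), c(0.9, 0.45, 0.95),
                   c("R", "extrasystole", "R"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(pk, f)
  back <- read_annotations(f)
  expect_equal(back$time, pk$time)
  expect_equal(back$norm_amp, pk$norm_amp)
  expect_identical(back$klass, pk$klass)

  write_annotations(rpeak_list(), f)
  expect_identical(readLines(f), "time_s\tclass\tnorm_amp")
  expect_equal(nrow(read_annotations(f)), 0)

  sim <- gen_ecg(ecg_sim_spec(60, hr_bpm = 60, seed = 1))
  write_annotations(sim$truth, f)
  expect_equal(nrow(read_annotations(f)), 60)
})

test_that("frame reassembly obeys the frame arithmetic and decodes heart rate", {
  ecgf <- function() list(kind = "ecg", payload = rnorm(63))
  brf <- function() list(kind = "breathing", payload = rnorm(18))
  set.seed(3)
  st <- frame_stream(c(replicate(4, ecgf(), simplify = FALSE),
                       replicate(2, brf(), simplify = FALSE)))
  out <- reassemble_frames(st)
  expect_equal(length(out$ecg$samples), 252L)       # 4 frames x 63
  expect_equal(ecg_duration(out$ecg), 251 / 250)    # spans ~1.008 s
  expect_equal(length(out$breathing$samples), 36L)  # 2 frames x 18

  empty <- reassemble_frames(frame_stream())
  expect_equal(length(empty$ecg$samples), 0L)
  expect_length(empty$heart_rate, 0)

  summ <- frame_stream(list(list(kind = "summary",
                                 payload = c(rep(0L, 12), 0x48, 0x00))))
  expect_equal(reassemble_frames(summ)$heart_rate, 72L)
  expect_equal(reassemble_frames(summ, hr_big_endian = TRUE)$heart_rate,
               0x48 * 256L)

  bad <- frame_stream(list(list(kind = "ecg", payload = rnorm(10))))
  expect_error(reassemble_frames(bad), "frame 1")
})
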