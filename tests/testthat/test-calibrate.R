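# Internal recalibration against CHO reference series.

make_offset_list <- function(ref, offset_ppm, noise_ppm = 0, seed = 1L,
                             drift_ppm = 0) {
  set.seed(seed)
  mz <- mz_deprotonated(ref, 1L)
  err <- offset_ppm + drift_ppm * (mz - 200) / 600 +
    rnorm(length(mz), 0, noise_ppm)
  mass_peaklist(mz * (1 + err * 1e-6), intensity = runif(length(mz), 1, 10),
                snr = rep(50, length(mz)))
}

test_that("a constant offset is removed to well under 0.5 ppm", {
  ref <- cho_reference_series(20L)
  pl <- make_offset_list(ref, offset_ppm = 1.5)
  cal <- recalibrate(pl, reference = ref)
  expect_identical(cal$calibration, "calibrated")
  err <- (cal$peaks$mz - mz_deprotonated(ref, 1L)) /
    mz_deprotonated(ref, 1L) * 1e6
  expect_lt(sqrt(mean(err^2)), 0.5)
  expect_lt(cal$calibration_rms_ppm, 0.5)
})

test_that("zero injected error leaves masses unchanged within 0.01 ppm", {
  ref <- cho_reference_series(20L)
  pl <- make_offset_list(ref, offset_ppm = 0)
  cal <- recalibrate(pl, reference = ref)
  shift <- abs(cal$peaks$mz - pl$peaks$mz) / pl$peaks$mz * 1e6
  expect_lt(max(shift), 0.01)
})

test_that("linear drift across the window is fitted out", {
  ref <- cho_reference_series(25L)
  pl <- make_offset_list(ref, offset_ppm = 0, drift_ppm = 2)
  cal <- recalibrate(pl, reference = ref)
  err <- (cal$peaks$mz - mz_deprotonated(ref, 1L)) /
    mz_deprotonated(ref, 1L) * 1e6
  expect_lt(sqrt(mean(err^2)), 0.3)
})

test_that("correction never raises the calibrant RMS (order <= 1 drifts)", {
  ref <- cho_reference_series(25L)
  for (s in 1:8) {
    pl <- make_offset_list(ref, offset_ppm = runif(1, -2, 2),
                           drift_ppm = runif(1, -1.5, 1.5),
                           noise_ppm = 0.2, seed = s)
    cal <- recalibrate(pl, reference = ref)
    expect_lte(cal$calibration_rms_ppm, attr(cal, "precal_rms_ppm") + 1e-9)
  }
})

test_that("calibration is refused below the minimum match count", {
  ref <- cho_reference_series(3L)
  pl <- make_offset_list(ref, offset_ppm = 1)
  expect_message(out <- recalibrate(pl, reference = ref), "refused")
  expect_identical(out$calibration, "raw")
  expect_identical(out$peaks$mz, pl$peaks$mz)
})

test_that("bootstrapped CHO CH2-series references calibrate a DOM spectrum", {
  ens <- generate_ensembles(small_design(7L))$samples[[2L]]
  pl <- generate_peaklist(ens, noise_ppm = 0.2, offset_ppm = 1.2, seed = 5L)
  pl <- filter_peaks(pl, 6)
  ref <- bootstrap_references(pl)
  expect_gt(nrow(ref), 10L)
  expect_true(all(ref$n == 0L & ref$s == 0L))
  cal <- recalibrate(pl, reference = ref)
  mz_true <- mz_deprotonated(ens, 1L)
  idx <- vapply(mz_true, function(m) which.min(abs(cal$peaks$mz - m)), 1L)
  err <- (cal$peaks$mz[idx] - mz_true) / mz_true * 1e6
  err <- err[abs(err) < 2]
  expect_lt(sqrt(mean(err^2)), 0.5)
})
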