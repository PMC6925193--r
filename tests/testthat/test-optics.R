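# Absorption descriptors and 1D fluorescence ratios.

test_that("absorption coefficient is 2.303 A / L", {
  sp <- absorption_spectrum(200:600, rep(0.1, 401), path_length_m = 0.01)
  expect_equal(absorption_coefficient(sp, 254), 23.03)
  sp0 <- absorption_spectrum(200:600, rep(0, 401), path_length_m = 0.05)
  expect_equal(absorption_coefficient(sp0, 400), 0)
  sp2 <- absorption_spectrum(200:600, rep(0.23, 401), path_length_m = 0.01)
  expect_equal(absorption_coefficient(sp2, 300), 52.969)
  expect_error(absorption_coefficient(sp, 254.5), "interpolate")
  expect_equal(absorption_coefficient(sp, 254.5, interpolate = TRUE), 23.03)
})

test_that("spectral slope recovers a noiseless exponential exactly", {
  lam <- 200:600
  a <- 5 * exp(-0.018 * (lam - 275))
  sp <- absorption_spectrum(lam, a * 0.01 / 2.303, path_length_m = 0.01)
  fit <- spectral_slope(sp, c(275, 295))
  expect_equal(fit$s, 0.018, tolerance = 1e-6)
  expect_equal(fit$a_ref, 5, tolerance = 1e-6)
  expect_gt(fit$r_squared, 0.999999)
  flat <- absorption_spectrum(lam, rep(0.05, length(lam)))
  expect_equal(spectral_slope(flat, c(300, 400))$s, 0, tolerance = 1e-12)
})

test_that("slope is within 5% of truth under 1% multiplicative noise", {
  ok <- 0
  for (s in 1:20) {
    sp <- generate_absorption(a440_true = 3, s_true = 0.016,
                              noise_frac = 0.01, seed = s)
    fit <- spectral_slope(sp, c(275, 295))
    if (abs(fit$s - 0.016) / 0.016 < 0.05) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("slope ratio is exactly 1 for single exponentials and > 1 with a steep UV term", {
  sp <- generate_absorption(a440_true = 4, s_true = 0.0165)
  expect_equal(slope_ratio(sp), 1, tolerance = 1e-9)
  two <- generate_absorption(a440_true = 4, s_true = 0.0165, uv_frac = 1.5)
  expect_gt(slope_ratio(two), 1)
})

test_that("carbon-specific absorbance is a homogeneous ratio", {
  expect_equal(specific_absorbance(46.06, 1), 46.06)
  expect_equal(specific_absorbance(23.03, 0.5), 46.06)
  expect_equal(specific_absorbance(2 * 46.06, 2), 46.06)
  expect_error(specific_absorbance(46.06, 0), "positive")
})

test_that("fluorescence intensity ratios read the right EEM cells", {
  em <- seq(300, 700, by = 5); ex <- seq(280, 410, by = 10)
  peak350 <- outer(dnorm(em, 350, 30), rep(1, length(ex)))
  e <- eem(peak350, ex = ex, em = em)
  fir <- fir_descriptors(e)
  expect_equal(fir[["f350_fmax"]], 1)
  sym <- outer(dnorm(em, 462.5, 60), rep(1, length(ex)))
  fir2 <- fir_descriptors(eem(sym, ex = ex, em = em))
  expect_equal(fir2[["f550_f375"]], 1, tolerance = 1e-12)
})

test_that("protein-like spectra score higher F350/Fmax than humic spectra", {
  des <- small_design()
  fl <- fluorophore_set(des)
  trp <- fl; trp$scores <- matrix(rep(c(10, 0.02, 0.02), 6), ncol = 3,
                                  byrow = TRUE)
  hum <- fl; hum$scores <- matrix(rep(c(0.02, 5, 5), 6), ncol = 3,
                                  byrow = TRUE)
  e_trp <- generate_eems(trp, noise_frac = 0, seed = 1)$eems[[1]]
  e_hum <- generate_eems(hum, noise_frac = 0, seed = 1)$eems[[1]]
  expect_gt(fir_descriptors(e_trp)[["f350_fmax"]],
            fir_descriptors(e_hum)[["f350_fmax"]])
})

test_that("spectra and EEMs round-trip through their text formats", {
  sp <- generate_absorption(3, 0.017, noise_frac = 0.01, seed = 2,
                            sample_id = "rt")
  p1 <- tempfile(fileext = ".tsv")
  write_absorption(sp, p1)
  back <- read_absorption(p1, sample_id = "rt")
  expect_equal(back$od, sp$od, tolerance = 1e-7)
  expect_equal(back$path_length_m, sp$path_length_m)
  e <- generate_eems(fluorophore_set(small_design()), seed = 3)$eems[[2]]
  p2 <- tempfile(fileext = ".tsv")
  write_eem(e, p2)
  eb <- read_eem(p2, sample_id = e$sample_id)
  expect_equal(eb$intensity, e$intensity, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(eb$ex, e$ex)
})
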