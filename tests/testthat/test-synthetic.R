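# The transect generator: determinism, planted structure, co-variation.

test_that("generators are bit-identical under a fixed seed", {
  d <- small_design(99L)
  g1 <- generate_ensembles(d); g2 <- generate_ensembles(d)
  expect_identical(g1, g2)
  p1 <- generate_peaklist(g1$samples[[1L]], seed = 5L)
  p2 <- generate_peaklist(g2$samples[[1L]], seed = 5L)
  expect_identical(p1$peaks, p2$peaks)
  e1 <- generate_eems(fluorophore_set(d), seed = 5L)
  e2 <- generate_eems(fluorophore_set(d), seed = 5L)
  expect_identical(e1$eems[[1L]]$intensity, e2$eems[[1L]]$intensity)
})

test_that("a single-class design yields a single-class ensemble", {
  w <- c(aliphatics = 0, n_saturated = 0, lignin_low_ox = 0,
         lignin_ox = 1, tannin_condensed = 0, tannin_hydrolysable = 0,
         carbohydrates = 0)
  d <- transect_design(n_stations = 4L, confluence_index = 2L,
                       shared_core = 120L, unique_per_south = 5L,
                       south_weights = w, north_weights = w, seed = 8L)
  g <- generate_ensembles(d)
  for (s in g$samples) {
    expect_true(all(classify(s) == "lignin_ox"))
  }
  expect_error(transect_design(south_weights = w * 0), "at least one class")
})

test_that("the oxidized-class gradient steps up across the confluence", {
  g <- generate_ensembles(transect_design(seed = 21L))
  dens <- g$truth$densities
  south <- g$truth$regime == "south"
  expect_gt(min(dens$tannin_hydrolysable[!south]),
            max(dens$tannin_hydrolysable[south]))
  expect_lt(max(dens$n_saturated[!south]), min(dens$n_saturated[south]))
  # CHO dominance by count
  shares <- vapply(g$samples,
                   function(s) stoichiometry_shares(s)[["pct_cho"]], 0)
  expect_true(all(shares > 80))
})

test_that("zero-noise peak lists round-trip through assignment completely", {
  ens <- generate_ensembles(small_design(31L))$samples[[2L]]
  pl <- generate_peaklist(ens, noise_ppm = 0, offset_ppm = 0,
                          n_noise_peaks = 0L, frac_z2 = 0, seed = 1L)
  pl$calibration <- "calibrated"  # nothing to correct by construction
  a <- assign_formulae(pl)
  expect_true(all(ens$key %in% formula_key(a)))
})

test_that("planted noise peaks sit at or below the S/N threshold", {
  ens <- generate_ensembles(small_design(37L))$samples[[1L]]
  pl <- generate_peaklist(ens, n_noise_peaks = 500L, seed = 2L)
  truth <- attr(pl, "truth")
  expect_equal(sum(truth$kind == "noise"), 500L)
  expect_true(all(truth$snr[truth$kind == "noise"] <= 6))
  kept <- filter_peaks(pl, 6)
  noise_mz <- truth$mz[truth$kind == "noise"]
  expect_false(any(round(kept$peaks$mz, 7) %in% round(noise_mz, 7)))
})

test_that("absorption truth is recovered at zero noise", {
  sp <- generate_absorption(a440_true = 3.5, s_true = 0.0172)
  fit <- spectral_slope(sp, c(350, 400))
  expect_equal(fit$s, 0.0172, tolerance = 1e-9)
  expect_equal(absorption_coefficient(sp, 440), 3.5, tolerance = 1e-9)
})

test_that("hydrochemistry co-varies with the planted molecular gradient", {
  d <- small_design(43L)
  g <- generate_ensembles(d)
  hyd <- generate_hydro(d, g$truth, noise_frac = 0, seed = 3L)
  expect_equal(cor(hyd$c_org, g$truth$densities$tannin_hydrolysable,
                   method = "spearman"), 1)
  hyd2 <- generate_hydro(d, g$truth, seed = 4L)
  m <- hydro_matrix(hyd2)
  expect_gt(m["c_org", "a254"], 0.7)
  expect_gt(abs(m["c_org", "ph"]), 0.7)
})

test_that("the planted gradient drives parameter selection, shuffling kills it", {
  d <- transect_design(n_stations = 12L, confluence_index = 6L,
                       shared_core = 600L, unique_per_south = 10L,
                       seed = 51L)
  g <- generate_ensembles(d)
  hyd <- generate_hydro(d, g$truth, seed = 6L)
  map <- spearman_map(g$samples, hyd)
  sel <- select_parameters(map, min_significant = 150L)
  expect_true("c_org" %in% sel)
  # destroy the pairing: no parameter keeps > 150 significant correlations
  shuf <- hyd
  set.seed(9L)
  shuf[, -1L] <- shuf[sample.int(nrow(shuf)), -1L]
  map0 <- spearman_map(g$samples, shuf)
  expect_length(select_parameters(map0, min_significant = 150L), 0L)
})
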