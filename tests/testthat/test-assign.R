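# Formula assignment: candidate search, ambiguity resolution, round trips.

test_that("a clean deprotonated mass is assigned its unique formula", {
  cand <- enumerate_candidates(419.098370, 1L, tol_ppm = 0.5)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand[1L, c("c", "h", "n", "o", "s")],
               data.frame(c = 20L, h = 20L, n = 0L, o = 10L, s = 0L),
               ignore_attr = TRUE)
})

test_that("peaks with no candidates are dropped and counted", {
  pl <- mass_peaklist(mz = c(419.098370, 300.000000),
                      intensity = c(1, 1), snr = c(50, 50),
                      calibration = "calibrated")
  a <- assign_formulae(pl, tol_ppm = 0.5)
  expect_equal(nrow(a), 1L)
  expect_equal(attr(a, "n_unassigned"), 1L)
})

test_that("assignment refuses uncalibrated input", {
  pl <- mass_peaklist(mz = 419.098370, intensity = 1, snr = 50)
  expect_error(assign_formulae(pl), "calibrated")
})

test_that("ambiguity resolution prefers fewest heteroatoms, then error", {
  cho <- cbind(molecular_formula(20, 20, 0, 10), error_ppm = 0.4)
  chnos <- cbind(molecular_formula(18, 24, 2, 9, 1), error_ppm = 0.1)
  pick <- resolve_ambiguity(rbind(cho, chnos))
  expect_equal(pick$n + pick$s, 0L)          # heteroatom rule precedes error
  one <- resolve_ambiguity(cho)
  expect_equal(one$c, 20L)
  tie <- rbind(cbind(molecular_formula(20, 20, 0, 10), error_ppm = 0.2),
               cbind(molecular_formula(21, 24, 0, 9), error_ppm = -0.2))
  expect_null(resolve_ambiguity(tie))        # exact |error| tie: ambiguous
})

test_that("optimized candidate search equals exhaustive enumeration", {
  set.seed(11)
  mzs <- runif(60, 200, 800)
  tols <- sample(c(0.5, 1), 60, replace = TRUE)
  for (i in seq_along(mzs)) {
    fast <- enumerate_candidates(mzs[i], 1L, tol_ppm = tols[i])
    expect_identical(sort(formula_key(fast)),
                     oracle_enumerate(mzs[i], tols[i]))
  }
})

test_that("zero-noise round trip recovers every resolvable formula", {
  set.seed(23)
  box <- formula_box()
  b <- box[(box$h - box$n) %% 2L == 0L & box$mass > 210 & box$mass < 790, ]
  # CHOS with O >= 14 collide with pure-CHO isobars within 0.25 ppm
  # (C21 vs H12O13S = 0.138 mDa) and are unresolvable by design
  b <- b[!(b$s == 1L & b$o >= 14L), ]
  idx <- sample(nrow(b), 500L)
  pl <- mass_peaklist(mz = sort(b$mass[idx]) - PROTON_MASS,
                      intensity = rep(1, 500), snr = rep(50, 500),
                      calibration = "calibrated")
  a <- assign_formulae(pl, tol_ppm = 0.5)
  expect_equal(nrow(a), 500L)
  expect_identical(sort(formula_key(a)), sort(formula_key(b[idx, ])))
})

test_that("ensemble recovery under light noise meets its noise-bound", {
  ens <- generate_ensembles(small_design(13L))$samples[[4L]]
  set.seed(31)
  mz <- mz_deprotonated(ens, 1L)
  mz_obs <- mz * (1 + rnorm(length(mz), 0, 0.2) * 1e-6)
  ord <- order(mz_obs)
  pl <- mass_peaklist(mz_obs[ord], intensity = ens$rel_intensity[ord],
                      snr = rep(50, length(mz)), calibration = "calibrated")
  a <- assign_formulae(pl, tol_ppm = 0.5)
  recovered <- mean(ens$key %in% formula_key(a))
  correct <- mean(formula_key(a) %in% ens$key)
  expect_gt(correct, 0.99)     # assignments almost never wrong
  expect_gt(recovered, 0.975)  # bounded by P(|N(0,0.2)| <= 0.5) = 0.988
})

test_that("charge > 1 never yields fractional atom counts", {
  # a z = 2 peak excluded from assignment cannot smuggle in a half-CH2
  ens <- generate_ensembles(small_design(17L))$samples[[1L]]
  pl <- generate_peaklist(ens, frac_z2 = 0.1, seed = 2L)
  pl <- drop_multicharged(determine_charge(filter_peaks(pl, 6)))
  expect_true(all(pl$peaks$charge == 1L))
})
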