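# Nonnegative trilinear decomposition of EEM stacks.

test_that("noiseless three-component EEMs are recovered almost exactly", {
  des <- transect_design(n_stations = 10L, confluence_index = 5L, seed = 2L)
  g <- generate_eems(fluorophore_set(des), noise_frac = 0, seed = 4L)
  m <- fit_trilinear(g$eems, 3L, seed = 7L, n_starts = 3L)
  cong <- model_congruence(m, g$truth$em_loadings, g$truth$ex_loadings)
  expect_gt(mean(cong), 0.99)
  expect_gt(m$variance_explained, 0.9999)
  # components ordered by ascending emission maximum
  em_max <- m$em[apply(m$em_loadings, 2L, which.max)]
  expect_false(is.unsorted(em_max))
})

test_that("a single-component stack is explained by one component", {
  des <- transect_design(n_stations = 8L, confluence_index = 4L, seed = 3L)
  fl <- fluorophore_set(des)
  fl$scores <- cbind(fl$scores[, 1L], 0, 0)
  g <- generate_eems(fl, noise_frac = 0, seed = 5L)
  m <- fit_trilinear(g$eems, 1L, seed = 1L, n_starts = 2L)
  expect_gt(m$variance_explained, 0.999)
})

test_that("the fit is invariant under sample reordering", {
  des <- transect_design(n_stations = 8L, confluence_index = 4L, seed = 6L)
  g <- generate_eems(fluorophore_set(des), noise_frac = 0.01, seed = 8L)
  m1 <- fit_trilinear(g$eems, 3L, seed = 9L, n_starts = 3L)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  m2 <- fit_trilinear(g$eems[perm], 3L, seed = 9L, n_starts = 3L)
  cong <- model_congruence(m2, m1$em_loadings, m1$ex_loadings)
  expect_gt(min(cong), 0.999)
  # scores follow the permutation (up to component matching)
  expect_equal(m2$sample_id, m1$sample_id[perm])
})

test_that("reconstruction error is non-increasing across ALS sweeps", {
  des <- transect_design(n_stations = 8L, confluence_index = 4L, seed = 10L)
  g <- generate_eems(fluorophore_set(des), noise_frac = 0.05, seed = 11L)
  m <- fit_trilinear(g$eems, 3L, seed = 12L, n_starts = 1L)
  tr <- m$loss_trace
  expect_true(all(diff(tr) <= 1e-8 * tr[-length(tr)]))
})

test_that("model selection finds three components and rejects a fourth", {
  des <- transect_design(n_stations = 20L, confluence_index = 10L,
                         seed = 2L)
  g <- generate_eems(fluorophore_set(des), noise_frac = 0.01, seed = 4L)
  sel <- suppressWarnings(select_components(g$eems, candidate_range = 2:4,
                                            seed = 5L, n_starts = 2L))
  expect_equal(as.integer(sel), 3L)
  expect_gt(attr(sel, "split_half")[["3"]], 0.95)
})

test_that("component ratios follow the score arithmetic", {
  m <- fake_model(matrix(1, 2, 3))
  r <- component_ratios(m)
  expect_equal(r$c1_c23, c(0.5, 0.5))
  expect_equal(r$c2_c123, c(1, 1) / 3)
  trp <- fake_model(matrix(c(10, 1, 1), 1, 3))
  expect_equal(component_ratios(trp)$c1_c23, 5)
  zero <- fake_model(matrix(c(0, 1, 1), 1, 3))
  expect_error(component_ratios(zero), "denominator")
})
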