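# Rank-correlation mapping and parameter selection.

make_hydro <- function(ids, c_org = NULL, seed = 1L) {
  set.seed(seed)
  n <- length(ids)
  hydro_table(data.frame(
    station_id = ids,
    temperature = rnorm(n, 22, 1), salinity = runif(n, 0.05, 0.1),
    ph = runif(n, 7, 8.5), alkalinity = runif(n, 1000, 3000),
    hco3 = runif(n, 900, 2900), co2 = runif(n, 30, 200),
    si = runif(n, 50, 120),
    c_org = if (is.null(c_org)) runif(n, 0.2, 1.1) else c_org,
    a254 = runif(n, 5, 35)))
}

mono_samples <- function(n_st, n_f = 6L) {
  # first formula rises with station index, the rest fall (relative
  # intensities sum to one, so they cannot all rise at once)
  f <- molecular_formula(10L + seq_len(n_f), 12L, 0L, 5L)
  lapply(seq_len(n_st), function(i) {
    sample_ensemble(f, c(i, rep(1, n_f - 1L)), sprintf("S%02d", i))
  })
}

test_that("perfect monotone association gives r = 1 and small p", {
  n <- 12L
  samples <- mono_samples(n)
  hydro <- make_hydro(sprintf("S%02d", 1:n), c_org = seq(0.2, 1.1,
                                                         length.out = n))
  map <- spearman_map(samples, hydro)
  sub <- map[map$parameter == "c_org", ]
  expect_equal(sub$r[sub$key == "C11H12O5"], 1)
  expect_true(all(sub$r[sub$key != "C11H12O5"] == -1))
  expect_true(all(sub$p < 0.05))
  # antisymmetry under order reversal of the parameter
  hydro2 <- hydro
  hydro2$c_org <- rev(seq(0.2, 1.1, length.out = n))
  map2 <- spearman_map(samples, hydro2)
  expect_equal(map2[map2$parameter == "c_org", "r"], -sub$r)
})

test_that("rho is invariant under strictly monotone transforms", {
  n <- 11L
  samples <- mono_samples(n)
  hydro <- make_hydro(sprintf("S%02d", 1:n), seed = 4L)
  m1 <- spearman_map(samples, hydro)
  hydro2 <- hydro
  hydro2$c_org <- exp(hydro2$c_org)      # strictly increasing transform
  m2 <- spearman_map(samples, hydro2)
  expect_equal(m1[m1$parameter == "c_org", "r"],
               m2[m2$parameter == "c_org", "r"])
})

test_that("p-values agree with cor.test in both regimes", {
  set.seed(8)
  # t-approximation regime
  x <- rnorm(15); y <- rnorm(15)
  rho <- cor(x, y, method = "spearman")
  expect_equal(spearman_pvalue(rho, 15L),
               cor.test(x, y, method = "spearman", exact = FALSE)$p.value,
               tolerance = 1e-10)
  # exact permutation regime
  x <- rnorm(7); y <- rnorm(7)
  rho <- cor(x, y, method = "spearman")
  expect_equal(spearman_pvalue(rho, 7L),
               cor.test(x, y, method = "spearman", exact = TRUE)$p.value,
               tolerance = 0.02)
})

test_that("constant vectors are excluded and mismatches refused", {
  n <- 8L
  samples <- mono_samples(n)
  # append a formula present everywhere with constant relative intensity
  samples2 <- lapply(seq_len(n), function(i) {
    s <- samples[[i]]
    f <- rbind(s[, c("c", "h", "n", "o", "s")],
               data.frame(c = 30L, h = 12L, n = 0L, o = 5L, s = 0L))
    sample_ensemble(molecular_formula(f$c, f$h, f$n, f$o, f$s),
                    c(s$rel_intensity, 0.5), attr(s, "sample_id"))
  })
  hydro <- make_hydro(sprintf("S%02d", 1:n))
  map <- spearman_map(samples2, hydro)
  expect_false("C30H12O5" %in% map$key)
  expect_gt(attr(map, "n_excluded_constant"), 0L)
  bad <- make_hydro(sprintf("X%02d", 1:n))
  expect_error(spearman_map(samples, bad), "match 1:1")
})

test_that("station exclusion is honoured", {
  n <- 9L
  samples <- mono_samples(n)
  hydro <- make_hydro(sprintf("S%02d", 1:n))
  map <- spearman_map(samples, hydro, exclude = "S05")
  expect_equal(attr(map, "n_stations"), 8L)
})

test_that("parameter selection counts significant correlations strictly", {
  n <- 12L
  samples <- mono_samples(n, n_f = 8L)
  hydro <- make_hydro(sprintf("S%02d", 1:n),
                      c_org = seq(0.2, 1.1, length.out = n), seed = 9L)
  map <- spearman_map(samples, hydro)
  sel <- select_parameters(map, min_significant = 7L)
  expect_true("c_org" %in% sel)
  expect_false("temperature" %in% select_parameters(map, 8L))
  # threshold is strict: a parameter with exactly 8 significant of 8 fails > 8
  expect_false("c_org" %in% select_parameters(map, 8L))
  all_sel <- select_parameters(map, 0L)
  expect_true(all(tapply(map$significant, map$parameter, sum)[all_sel] >= 1))
})

test_that("overlay highlighting uses strict thresholds", {
  map <- structure(data.frame(parameter = "c_org",
                              key = c("A", "B", "C"),
                              oc = c(0.6, 0.3, 0.7), hc = c(0.5, 1.2, 0.6),
                              r = c(0.70, -0.9, 0.71),
                              p = c(0.01, 0.001, 0.02),
                              significant = TRUE),
                   class = c("correlation_map", "data.frame"),
                   n_stations = 18L, alpha = 0.05)
  ov <- vk_overlay(map, "c_org", r_threshold = 0.7)
  expect_equal(ov$highlight, c("weak", "strong_neg", "strong_pos"))
  expect_error(vk_overlay(map, "nope"), "not present")
})

test_that("the hydrochemistry matrix is symmetric with unit diagonal", {
  hydro <- make_hydro(sprintf("S%02d", 1:8), seed = 3L)
  hydro$a254 <- hydro$c_org   # duplicated column
  m <- hydro_matrix(hydro)
  expect_equal(diag(m), rep(1, ncol(m)), ignore_attr = TRUE)
  expect_equal(m, t(m))
  expect_equal(m["c_org", "a254"], 1)
  expect_error(hydro_matrix(make_hydro(sprintf("S%02d", 1:4))), "at least 5")
})
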