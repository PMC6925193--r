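# Compound-class profiling, densities, descriptors, set operations.

test_that("classification follows the printed stoichiometric regions", {
  expect_equal(as.character(classify(molecular_formula(10, 20, 0, 2))),
               "aliphatics")            # O/C 0.2, H/C 2.0
  expect_equal(as.character(classify(molecular_formula(10, 12, 0, 7))),
               "lignin_ox")             # O/C 0.7, H/C 1.2
  # overlap: N >= 1 with O/C 0.417, H/C 1.833 is N-saturated, not aliphatic
  expect_equal(as.character(classify(molecular_formula(12, 22, 1, 5))),
               "n_saturated")
  expect_equal(as.character(classify(molecular_formula(10, 5, 0, 3))),
               "tannin_condensed")      # O/C 0.3, H/C 0.5
  expect_equal(as.character(classify(molecular_formula(10, 5, 0, 7))),
               "tannin_hydrolysable")   # O/C 0.7, H/C 0.5
  expect_equal(as.character(classify(molecular_formula(10, 17, 0, 7))),
               "carbohydrates")         # O/C 0.7, H/C 1.7
  expect_equal(as.character(classify(molecular_formula(10, 2, 0, 1))),
               "unclassified")          # H/C 0.2 below every region
})

test_that("boundary membership matches the printed open/closed sides", {
  # O/C = 0.5 exactly: closed for oxidized lignin, open (excluded) for low-ox
  expect_equal(as.character(classify(molecular_formula(10, 10, 0, 5))),
               "lignin_ox")
  # H/C = 0.7 exactly: closed for lignins, open for tannins
  expect_equal(as.character(classify(molecular_formula(10, 7, 1, 3))),
               "lignin_low_ox")
  # H/C = 1.6 exactly: closed for aliphatics, open for lignins
  expect_equal(as.character(classify(molecular_formula(10, 16, 0, 2))),
               "aliphatics")
  # O/C = 0.65 exactly: closed for carbohydrates, open for aliphatics
  expect_equal(as.character(classify(molecular_formula(20, 34, 0, 13))),
               "carbohydrates")         # H/C 1.7, outside the lignin overlap
  # H/C = 1.0 exactly with N: closed for the N-saturated floor
  expect_equal(as.character(classify(molecular_formula(10, 10, 2, 3))),
               "n_saturated")
  # O/C = 0.1 exactly: closed for low-ox lignin
  expect_equal(as.character(classify(molecular_formula(20, 16, 0, 2))),
               "lignin_low_ox")
})

test_that("densities form a partition and obey the intensity quotient", {
  one <- sample_ensemble(molecular_formula(10, 12, 0, 7), 3, "a")
  d <- class_densities(one)
  expect_equal(d$lignin_ox, 1)
  expect_equal(sum(d[, COMPOUND_CLASSES]), 1)
  two <- sample_ensemble(molecular_formula(c(10, 10), c(12, 20), 0,
                                           c(7, 2)),
                         c(0.25, 0.75), "b")
  d2 <- class_densities(two)
  expect_equal(d2$lignin_ox, 0.25)
  expect_equal(d2$aliphatics, 0.75)
})

test_that("densities are scale-invariant and sum to one on random ensembles", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    f <- molecular_formula(c = sample(5:40, n, TRUE),
                           h = sample(2:70, n, TRUE),
                           n = sample(0:2, n, TRUE),
                           o = sample(1:30, n, TRUE),
                           s = sample(0:1, n, TRUE))
    raw <- runif(n, 0.1, 10)
    e1 <- sample_ensemble(f, raw, "x")
    e2 <- sample_ensemble(f, raw * 1234.5, "x")
    d1 <- class_densities(e1); d2 <- class_densities(e2)
    expect_equal(sum(d1[, COMPOUND_CLASSES]), 1, tolerance = 1e-9)
    expect_equal(d1, d2, tolerance = 1e-12)
  }
})

test_that("family shares are count-based percentages", {
  all_cho <- sample_ensemble(molecular_formula(10:14, 12, 0, 5), rep(1, 5))
  expect_equal(unname(stoichiometry_shares(all_cho)), c(100, 0, 0, 0))
  mix <- sample_ensemble(molecular_formula(c(10:17, 18, 19),
                                           h = 12,
                                           n = c(rep(0, 8), 1, 0),
                                           o = 5,
                                           s = c(rep(0, 9), 1)),
                         rep(1, 10))
  expect_equal(unname(stoichiometry_shares(mix)), c(80, 10, 10, 0))
})

test_that("number-averaged descriptors are unweighted means", {
  f <- molecular_formula(c(16, 20), c(18, 18), 0, c(9, 11))
  e <- sample_ensemble(f, c(0.9, 0.1), "m")
  row <- number_averaged(e)
  expect_equal(row$dbe_n, mean(dbe(f)))
  expect_equal(row$oc_n, mean(f$oc))
  expect_equal(row$m_n, mean(f$mass))
  single <- sample_ensemble(molecular_formula(16, 18, 0, 9), 1, "s")
  r1 <- number_averaged(single)
  expect_equal(r1$dbe_n, 8)
  # intensity-weighted variant shifts toward the heavy member
  rw <- number_averaged(e, intensity_weighted = TRUE)
  expect_lt(rw$m_n, row$m_n)
})

test_that("common and unique formula subspaces behave as set operations", {
  f1 <- molecular_formula(c(10, 11, 12), 12, 0, 5)
  f2 <- molecular_formula(c(11, 12, 13), 12, 0, 5)
  s1 <- sample_ensemble(f1, rep(1, 3), "s1")
  s2 <- sample_ensemble(f2, rep(1, 3), "s2")
  expect_equal(nrow(common_formulae(list(s1, s1))), 3L)
  disjoint <- sample_ensemble(molecular_formula(20:22, 12, 0, 5),
                              rep(1, 3), "s3")
  expect_equal(nrow(common_formulae(list(s1, disjoint))), 0L)
  u <- unique_formulae(list(s1, s2, s2))
  # C10 occurs once (unique to s1); C11/C12 occur 3x (nowhere unique)
  expect_equal(formula_key(u[["s1"]]), "C10H12O5")
  expect_equal(nrow(u[["s2"]]), 1L)  # C13 occurs twice (<= 2)
})

test_that("generator ground truth is recovered by the set operations", {
  g <- generate_ensembles(small_design(3L))
  cm <- common_formulae(g$samples)
  expect_equal(sort(formula_key(cm)), sort(g$truth$core$key))
  u <- unique_formulae(g$samples)
  for (i in 1:3) {
    expect_setequal(formula_key(u[[i]]), g$truth$unique_keys[[i]])
  }
  # common is contained in every sample; unique disjoint from common
  for (s in g$samples) {
    expect_true(all(formula_key(cm) %in% s$key))
  }
  expect_length(intersect(unlist(lapply(u, formula_key)),
                          formula_key(cm)), 0L)
})

test_that("the Van Krevelen table is consistent with classification", {
  e <- generate_ensembles(small_design(29L))$samples[[1L]]
  vk <- vk_table(e)
  expect_equal(nrow(vk), nrow(e))
  expect_identical(as.character(vk$class),
                   as.character(classify(parse_formula_key(vk$key))))
  expect_false(is.unsorted(vk$oc))
})
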