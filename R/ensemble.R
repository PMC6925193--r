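# Van Krevelen compound-class profiling of assigned molecular ensembles.

#' Compound-class labels
#'
#' The seven stoichiometric Van Krevelen regions plus an explicit
#' `unclassified` label so that class densities always form a partition.
#'
#' @format Character vector of the eight labels in reporting order.
#' @export
COMPOUND_CLASSES <- c("aliphatics", "n_saturated", "lignin_low_ox",
                      "lignin_ox", "tannin_condensed", "tannin_hydrolysable",
                      "carbohydrates", "unclassified")

#' Construct a sample ensemble
#'
#' A sample's assigned formulae with sum-normalized relative intensities —
#' the unit of all downstream statistics. Duplicate formulae (same CHNOS
#' tuple) are collapsed by summing intensity before normalization.
#'
#' @param formulae A `molform_tbl` (e.g. the formula columns of an
#'   `assignment_tbl`).
#' @param intensity Raw intensities, one per formula row.
#' @param sample_id Sample identifier.
#' @return An object of class `sample_ensemble`: a data.frame with the
#'   formula columns, `rel_intensity` (summing to 1) and a `key` column;
#'   attribute `sample_id`.
#' @export
sample_ensemble <- function(formulae, intensity, sample_id = "sample") {
  stopifnot(nrow(formulae) == length(intensity))
  if (nrow(formulae) == 0L) stop("ensemble must contain at least one formula")
  if (any(intensity <= 0)) stop("intensities must be positive")
  df <- as.data.frame(formulae)[, c("c", "h", "n", "o", "s")]
  df$intensity <- intensity
  key <- formula_key(df)
  if (anyDuplicated(key)) {
    df <- stats::aggregate(intensity ~ c + h + n + o + s, data = df, FUN = sum)
  }
  out <- molecular_formula(df$c, df$h, df$n, df$o, df$s)
  out$rel_intensity <- df$intensity / sum(df$intensity)
  out$key <- formula_key(out)
  out <- out[order(out$mass), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sample_ensemble", "molform_tbl", "data.frame")
  attr(out, "sample_id") <- sample_id
  out
}

#' Ensemble from an assignment table
#'
#' @param a An `assignment_tbl` from [assign_formulae()].
#' @return A `sample_ensemble` with the assignment's sample id.
#' @export
as_sample_ensemble <- function(a) {
  stopifnot(inherits(a, "assignment_tbl"))
  sample_ensemble(a[, c("c", "h", "n", "o", "s")], a$intensity,
                  sample_id = attr(a, "sample_id"))
}

#' Classify a formula into its Van Krevelen compound class
#'
#' Stoichiometric regions in (O/C, H/C) space, boundaries exactly as
#' conventionally printed (left-closed/right-open where stated):
#' aliphatics (0 < O/C < 0.65, 1.6 <= H/C < 2.2); N-saturated (peptides and
#' amino-sugars: N >= 1, 0.1 <= O/C < 0.65, 1 <= H/C < 2.2); low-oxidized
#' lignins (0.1 <= O/C < 0.5, 0.7 <= H/C < 1.6); oxidized lignins
#' (0.5 <= O/C < 1, 0.7 <= H/C < 1.6); condensed tannins (0 < O/C < 0.5,
#' 0.3 <= H/C < 0.7); hydrolysable tannins (0.5 <= O/C < 1,
#' 0.3 <= H/C < 0.7); carbohydrates (0.65 <= O/C < 1, 1.3 <= H/C < 2.2).
#' The N-saturated rule is evaluated first for N-containing formulae (its
#' region overlaps the aliphatic and lignin boxes; presence of N defines
#' the class), then the N-free regions in the printed order. Anything that
#' matches no region is `unclassified`.
#'
#' @param formula A `molform_tbl` (vectorised over rows).
#' @return Factor with levels [COMPOUND_CLASSES].
#' @export
classify <- function(formula) {
  oc <- formula$o / formula$c
  hc <- formula$h / formula$c
  n <- formula$n
  lab <- rep("unclassified", nrow(formula))
  # printed order; first match wins via filling only unset slots
  rules <- list(
    n_saturated = n >= 1L & oc >= 0.1 & oc < 0.65 & hc >= 1 & hc < 2.2,
    aliphatics = oc > 0 & oc < 0.65 & hc >= 1.6 & hc < 2.2,
    lignin_low_ox = oc >= 0.1 & oc < 0.5 & hc >= 0.7 & hc < 1.6,
    lignin_ox = oc >= 0.5 & oc < 1 & hc >= 0.7 & hc < 1.6,
    tannin_condensed = oc > 0 & oc < 0.5 & hc >= 0.3 & hc < 0.7,
    tannin_hydrolysable = oc >= 0.5 & oc < 1 & hc >= 0.3 & hc < 0.7,
    carbohydrates = oc >= 0.65 & oc < 1 & hc >= 1.3 & hc < 2.2
  )
  for (cl in names(rules)) {
    hit <- rules[[cl]] & lab == "unclassified"
    lab[hit] <- cl
  }
  factor(lab, levels = COMPOUND_CLASSES)
}

#' Intensity-weighted compound-class densities
#'
#' Population density of class k: D_k = (sum of relative intensities of the
#' class members) / (total relative intensity) — so the eight labels always
#' sum to one; the conventional seven-class report simply omits the
#' unclassified remainder.
#'
#' @param ensemble A `sample_ensemble`.
#' @return A one-row data.frame: `sample_id` plus one density column per
#'   label in [COMPOUND_CLASSES].
#' @export
class_densities <- function(ensemble) {
  stopifnot(inherits(ensemble, "sample_ensemble"))
  cl <- classify(ensemble)
  d <- vapply(COMPOUND_CLASSES,
              function(k) sum(ensemble$rel_intensity[cl == k]), 0) /
    sum(ensemble$rel_intensity)
  out <- as.data.frame(as.list(d))
  names(out) <- COMPOUND_CLASSES
  cbind(data.frame(sample_id = attr(ensemble, "sample_id")), out)
}

#' Heteroatom-family shares by count
#'
#' Percentage of assignments (by count, not intensity) in each of the
#' mutually exclusive families CHO, CHON, CHOS, CHNOS.
#'
#' @param ensemble A `sample_ensemble`.
#' @return Named numeric vector `pct_cho`, `pct_chon`, `pct_chos`,
#'   `pct_chnos` summing to 100.
#' @export
stoichiometry_shares <- function(ensemble) {
  fam <- heteroatom_family(ensemble)
  shares <- 100 * vapply(c("CHO", "CHON", "CHOS", "CHNOS"),
                         function(f) mean(fam == f), 0)
  names(shares) <- c("pct_cho", "pct_chon", "pct_chos", "pct_chnos")
  shares
}

#' Number-averaged molecular descriptors
#'
#' One row of the per-sample descriptor table: assignment count, family
#' shares, and the unweighted arithmetic means over formulae of neutral
#' monoisotopic mass, O/C, H/C and DBE. An intensity-weighted variant is
#' available for sensitivity analysis.
#'
#' @param ensemble A `sample_ensemble`.
#' @param intensity_weighted Use relative intensities as weights instead of
#'   the (default) unweighted means.
#' @return A one-row data.frame: `sample_id`, `n_formulae`, `pct_cho`,
#'   `pct_chon`, `pct_chos`, `pct_chnos`, `m_n`, `oc_n`, `hc_n`, `dbe_n`.
#' @export
number_averaged <- function(ensemble, intensity_weighted = FALSE) {
  stopifnot(inherits(ensemble, "sample_ensemble"))
  w <- if (intensity_weighted) ensemble$rel_intensity else
    rep(1 / nrow(ensemble), nrow(ensemble))
  w <- w / sum(w)
  sh <- stoichiometry_shares(ensemble)
  data.frame(sample_id = attr(ensemble, "sample_id"),
             n_formulae = nrow(ensemble),
             pct_cho = sh[["pct_cho"]], pct_chon = sh[["pct_chon"]],
             pct_chos = sh[["pct_chos"]], pct_chnos = sh[["pct_chnos"]],
             m_n = sum(w * ensemble$mass), oc_n = sum(w * ensemble$oc),
             hc_n = sum(w * ensemble$hc), dbe_n = sum(w * ensemble$dbe))
}

#' Formulae common to every sample
#'
#' Exact intersection of the samples' formula sets (CHNOS identity).
#'
#' @param samples A list of `sample_ensemble` objects (>= 2).
#' @return A `molform_tbl` of the shared formulae, sorted by mass.
#' @export
common_formulae <- function(samples) {
  stopifnot(length(samples) >= 2L)
  keys <- lapply(samples, function(s) s$key)
  shared <- Reduce(intersect, keys)
  out <- parse_formula_key(shared)
  out <- out[order(out$mass), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Formulae unique to few samples
#'
#' For each sample, its formulae whose occurrence count across the whole
#' sample set is at most `max_occurrence` (default 2).
#'
#' @param samples A list of `sample_ensemble` objects (>= 3).
#' @param max_occurrence Largest occurrence count still called unique.
#' @return Named list (by sample id) of `molform_tbl`s.
#' @export
unique_formulae <- function(samples, max_occurrence = 2L) {
  stopifnot(length(samples) >= 3L)
  keys <- lapply(samples, function(s) s$key)
  occ <- table(unlist(keys))
  rare <- names(occ)[occ <= max_occurrence]
  out <- lapply(samples, function(s) {
    k <- s$key[s$key %in% rare]
    parse_formula_key(k)
  })
  names(out) <- vapply(samples, function(s) attr(s, "sample_id"), "")
  out
}

#' Van Krevelen table for plotting/export
#'
#' One row per formula with its Van Krevelen coordinates, relative
#' intensity, compound class and heteroatom family, deterministically
#' ordered by (O/C, H/C, mass).
#'
#' @param ensemble A `sample_ensemble`.
#' @return A data.frame with columns `key`, `oc`, `hc`, `mass`,
#'   `intensity`, `class`, `family`.
#' @export
vk_table <- function(ensemble) {
  stopifnot(inherits(ensemble, "sample_ensemble"))
  out <- data.frame(key = ensemble$key, oc = ensemble$oc, hc = ensemble$hc,
                    mass = ensemble$mass, intensity = ensemble$rel_intensity,
                    class = classify(ensemble),
                    family = heteroatom_family(ensemble))
  out <- out[order(out$oc, out$hc, out$mass), , drop = FALSE]
  rownames(out) <- NULL
  out
}
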