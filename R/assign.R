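# Elemental formula assignment for singly charged [M - H]- DOM ions.
#
# The production search enumerates the full atomic-constraint box once
# (masses up to the acquisition window plus a margin), sorts it by neutral
# mass, and resolves each peak by binary search. At sub-ppm tolerances the
# candidate set per peak is tiny, so one cached enumeration plus
# findInterval is both exact and fast.

.box_cache <- new.env(parent = emptyenv())

#' Atomic constraints for DOM formula assignment
#'
#' The constraint box conventionally applied to riverine/marine DOM:
#' O/C <= 1, H/C <= 2, C <= 120, H <= 200, 0 < O <= 60, N <= 2, S <= 1.
#'
#' @param max_c,max_h,max_n,max_s Upper atom-count bounds.
#' @param o_range Inclusive bounds on oxygen count; the lower bound is 1
#'   (every DOM formula carries oxygen).
#' @param oc_max,hc_max Elemental ratio caps.
#' @param tol_ppm Assignment tolerance (ppm) carried with the constraint
#'   set for configuration round-trips.
#' @param snr_min S/N threshold carried for configuration round-trips.
#' @return A list of class `atomic_constraints`.
#' @export
atomic_constraints <- function(max_c = 120L, max_h = 200L, max_n = 2L,
                               max_s = 1L, o_range = c(1L, 60L),
                               oc_max = 1, hc_max = 2,
                               tol_ppm = 0.5, snr_min = 6) {
  structure(list(max_c = as.integer(max_c), max_h = as.integer(max_h),
                 max_n = as.integer(max_n), max_s = as.integer(max_s),
                 o_range = as.integer(o_range), oc_max = oc_max,
                 hc_max = hc_max, tol_ppm = tol_ppm, snr_min = snr_min),
            class = "atomic_constraints")
}

#' Enumerate the full constraint box
#'
#' All CHNOS formulae satisfying the atomic constraints with non-negative
#' DBE and neutral mass at most `mass_max`, sorted by mass. The result is
#' cached per (constraints, mass_max) within a session.
#'
#' @param constraints An [atomic_constraints()] set.
#' @param mass_max Largest neutral mass retained (Da); default covers an
#'   800 Da acquisition window with margin.
#' @return A `molform_tbl` sorted by `mass`.
#' @export
formula_box <- function(constraints = atomic_constraints(), mass_max = 820) {
  key <- paste(unlist(constraints[c("max_c", "max_h", "max_n", "max_s",
                                    "o_range", "oc_max", "hc_max")]),
               collapse = "_")
  key <- paste0(key, "_", format(mass_max))
  if (!is.null(.box_cache[[key]])) return(.box_cache[[key]])
  cs <- constraints
  max_c_eff <- min(cs$max_c, floor(mass_max / ISOTOPE_MASS[["C"]]))
  pieces <- vector("list", max_c_eff)
  ns <- expand.grid(n = 0:cs$max_n, s = 0:cs$max_s)
  for (cc in seq_len(max_c_eff)) {
    h_max <- min(cs$max_h, floor(cs$hc_max * cc))
    o_max <- min(cs$o_range[2L], floor(cs$oc_max * cc))
    if (h_max < 1L || o_max < cs$o_range[1L]) next
    g <- expand.grid(h = seq_len(h_max), o = cs$o_range[1L]:o_max,
                     n = 0:cs$max_n, s = 0:cs$max_s)
    g$c <- cc
    mass <- cc * ISOTOPE_MASS[["C"]] + g$h * ISOTOPE_MASS[["H"]] +
      g$n * ISOTOPE_MASS[["N"]] + g$o * ISOTOPE_MASS[["O"]] +
      g$s * ISOTOPE_MASS[["S"]]
    keep <- mass <= mass_max & dbe_from_counts(cc, g$h, g$n) >= 0
    g <- g[keep, c("c", "h", "n", "o", "s")]
    g$mass <- mass[keep]
    pieces[[cc]] <- g
  }
  box <- do.call(rbind, pieces)
  box <- box[order(box$mass), , drop = FALSE]
  rownames(box) <- NULL
  box$oc <- box$o / box$c
  box$hc <- box$h / box$c
  box$dbe <- dbe_from_counts(box$c, box$h, box$n)
  class(box) <- c("molform_tbl", "data.frame")
  .box_cache[[key]] <- box
  box
}

#' Candidate formulae for one observed m/z
#'
#' Neutral CHNOS formulae whose deprotonated m/z lies within `tol_ppm` of
#' the observation and which satisfy every atomic constraint, non-negative
#' DBE and — for even-electron [M - zH]- ions — integer DBE (H - N even).
#'
#' @param mz Observed m/z (scalar).
#' @param charge Ion charge (protons removed); default 1.
#' @param constraints An [atomic_constraints()] set.
#' @param tol_ppm Matching tolerance in ppm.
#' @param box Optional precomputed [formula_box()].
#' @return A `molform_tbl` with an `error_ppm` column (observed minus
#'   theoretical, in ppm), possibly empty.
#' @export
enumerate_candidates <- function(mz, charge = 1L,
                                 constraints = atomic_constraints(),
                                 tol_ppm = constraints$tol_ppm,
                                 box = NULL) {
  if (is.null(box)) box <- formula_box(constraints)
  m_neutral <- mz * charge + charge * PROTON_MASS
  lo <- m_neutral * (1 - tol_ppm * 1e-6)
  hi <- m_neutral * (1 + tol_ppm * 1e-6)
  i0 <- findInterval(lo, box$mass) + 1L
  i1 <- findInterval(hi, box$mass)
  if (i1 < i0) {
    out <- box[0L, ]
    out$error_ppm <- numeric(0)
    return(out)
  }
  out <- box[i0:i1, , drop = FALSE]
  out <- out[(out$h - out$n) %% 2L == 0L & out$h >= charge, , drop = FALSE]
  out$error_ppm <- (m_neutral - out$mass) / out$mass * 1e6
  rownames(out) <- NULL
  out
}

#' Resolve an ambiguous candidate set
#'
#' If one candidate, return it. Otherwise prefer, in order: (1) fewest
#' heteroatoms N + S; (2) smallest absolute mass error. A remaining tie is
#' unresolvable: the peak is marked ambiguous (and later excluded from
#' correlation analysis).
#'
#' @param candidates A `molform_tbl` with an `error_ppm` column.
#' @return The single-row winning candidate, or `NULL` when no candidate or
#'   an unresolvable tie remains.
#' @export
resolve_ambiguity <- function(candidates) {
  if (nrow(candidates) == 0L) return(NULL)
  if (nrow(candidates) == 1L) return(candidates)
  het <- candidates$n + candidates$s
  candidates <- candidates[het == min(het), , drop = FALSE]
  if (nrow(candidates) == 1L) return(candidates)
  aerr <- abs(candidates$error_ppm)
  candidates <- candidates[aerr == min(aerr), , drop = FALSE]
  if (nrow(candidates) == 1L) return(candidates)
  NULL
}

#' Assign elemental formulae to a calibrated peak list
#'
#' For each singly charged peak, enumerates all in-constraint candidates
#' within `tol_ppm` of the deprotonated mass and keeps at most one after
#' [resolve_ambiguity()]. Unassignable peaks are omitted but counted.
#'
#' @param x A calibrated `mass_peaklist` (assignment refuses raw lists).
#' @param constraints An [atomic_constraints()] set (defaults are the
#'   standard DOM bounds).
#' @param tol_ppm Post-calibration matching tolerance, default 0.5 ppm.
#' @return A data.frame of class `assignment_tbl`: one row per assigned
#'   peak with `mz`, `intensity`, `snr`, the formula columns, `error_ppm`
#'   and `candidates_considered`; attributes `n_unassigned`, `n_ambiguous`,
#'   `sample_id`.
#' @export
assign_formulae <- function(x, constraints = atomic_constraints(),
                            tol_ppm = constraints$tol_ppm) {
  stopifnot(inherits(x, "mass_peaklist"))
  if (x$calibration != "calibrated") {
    stop("peak list must be internally calibrated before assignment")
  }
  pk <- x$peaks
  single <- is.na(pk$charge) | pk$charge == 1L
  pk <- pk[single, , drop = FALSE]
  box <- formula_box(constraints)
  m_neutral <- pk$mz + PROTON_MASS
  i0 <- findInterval(m_neutral * (1 - tol_ppm * 1e-6), box$mass) + 1L
  i1 <- findInterval(m_neutral * (1 + tol_ppm * 1e-6), box$mass)
  n_cand <- pmax(i1 - i0 + 1L, 0L)
  rows <- vector("list", nrow(pk))
  n_unassigned <- 0L
  n_ambiguous <- 0L
  for (i in seq_len(nrow(pk))) {
    if (n_cand[i] == 0L) { n_unassigned <- n_unassigned + 1L; next }
    cand <- box[i0[i]:i1[i], , drop = FALSE]
    cand <- cand[(cand$h - cand$n) %% 2L == 0L & cand$h >= 1L, , drop = FALSE]
    if (nrow(cand) == 0L) { n_unassigned <- n_unassigned + 1L; next }
    cand$error_ppm <- (m_neutral[i] - cand$mass) / cand$mass * 1e6
    win <- resolve_ambiguity(cand)
    if (is.null(win)) { n_ambiguous <- n_ambiguous + 1L; next }
    win$candidates_considered <- nrow(cand)
    win$peak_row <- i
    rows[[i]] <- win
  }
  hits <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(hits)) {
    hits <- cbind(box[0L, ], error_ppm = numeric(0),
                  candidates_considered = integer(0), peak_row = integer(0))
  }
  out <- cbind(pk[hits$peak_row, c("mz", "intensity", "snr")],
               hits[, c("c", "h", "n", "o", "s", "oc", "hc", "dbe", "mass",
                        "error_ppm", "candidates_considered")])
  rownames(out) <- NULL
  structure(out, class = c("assignment_tbl", "data.frame"),
            n_unassigned = n_unassigned, n_ambiguous = n_ambiguous,
            sample_id = x$sample_id)
}
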