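# Internal mass recalibration against known DOM peak series.
#
# DOM spectra carry dense CH2-homologous CHO series; their unambiguous
# coarse assignments provide hundreds of internal calibrants spanning the
# acquisition window. A low-order (linear in m/z) ppm-error model fitted to
# the matched calibrants removes systematic offset and drift.

#' Bootstrap a CHO calibration reference series from the spectrum itself
#'
#' Coarse-assigns the most abundant peaks (CHO only, wide tolerance), keeps
#' unambiguous hits, and retains formulae belonging to CH2 homologous
#' series with at least `min_series` members. Adding CH2 leaves (O, H-2C)
#' invariant, which is the series key.
#'
#' @param x A `mass_peaklist`.
#' @param n_top Number of most intense peaks coarse-assigned (default 400).
#' @param coarse_ppm Coarse matching window in ppm (default 3).
#' @param min_series Minimum members per retained CH2 series (default 3).
#' @param constraints An [atomic_constraints()] set.
#' @return A `molform_tbl` of reference formulae (possibly empty).
#' @export
bootstrap_references <- function(x, n_top = 400L, coarse_ppm = 3,
                                 min_series = 3L,
                                 constraints = atomic_constraints()) {
  stopifnot(inherits(x, "mass_peaklist"))
  pk <- x$peaks
  pk <- pk[is.na(pk$charge) | pk$charge == 1L, , drop = FALSE]
  pk <- pk[order(-pk$intensity), , drop = FALSE]
  pk <- utils::head(pk, n_top)
  cho <- atomic_constraints(max_c = constraints$max_c,
                            max_h = constraints$max_h,
                            max_n = 0L, max_s = 0L,
                            o_range = constraints$o_range,
                            oc_max = constraints$oc_max,
                            hc_max = constraints$hc_max)
  box <- formula_box(cho)
  hits <- vector("list", nrow(pk))
  for (i in seq_len(nrow(pk))) {
    cand <- enumerate_candidates(pk$mz[i], 1L, cho, tol_ppm = coarse_ppm,
                                 box = box)
    if (nrow(cand) == 1L) hits[[i]] <- cand
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(hits) || nrow(hits) == 0L) {
    return(molecular_formula(c = 1L, h = 2L, o = 1L)[0L, ])
  }
  series <- paste(hits$o, hits$h - 2L * hits$c, sep = "/")
  keep <- series %in% names(which(table(series) >= min_series))
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[!duplicated(formula_key(hits)), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("c", "h", "n", "o", "s", "oc", "hc", "dbe", "mass")]
}

#' Internally recalibrate a peak list
#'
#' Matches reference formulae (their deprotonated m/z) to observed peaks
#' within a coarse window, fits the ppm error as a low-order polynomial in
#' m/z by ordinary least squares (default linear), applies the correction
#' to every peak, and records the residual RMS of the matched calibrants in
#' ppm. Because the fitted model nests the zero (no-op) correction, the
#' residual RMS never exceeds the pre-correction RMS. With fewer than
#' `min_matches` calibrants the calibration is refused and the list
#' returned unchanged with a message.
#'
#' @param x A `mass_peaklist`.
#' @param reference A `molform_tbl` of reference formulae, or `NULL` to
#'   bootstrap a CHO CH2-series set from the spectrum itself.
#' @param coarse_ppm Matching window for calibrant pairing (default 3 ppm).
#' @param degree Polynomial degree of the ppm-error model (0 or 1;
#'   default 1).
#' @param min_matches Minimum calibrant matches required (default 5).
#' @return A calibrated `mass_peaklist` with `calibration_rms_ppm` set and
#'   attributes `n_calibrants`, `precal_rms_ppm`.
#' @export
recalibrate <- function(x, reference = NULL, coarse_ppm = 3, degree = 1L,
                        min_matches = 5L) {
  stopifnot(inherits(x, "mass_peaklist"))
  if (is.null(reference)) reference <- bootstrap_references(x)
  if (nrow(reference) > 0L) {
    ref_mz <- mz_deprotonated(reference, 1L)
    obs <- x$peaks$mz
    idx <- findInterval(ref_mz, obs)
    best <- pmin(pmax(idx, 1L), length(obs))
    alt <- pmin(best + 1L, length(obs))
    use_alt <- abs(obs[alt] - ref_mz) < abs(obs[best] - ref_mz)
    best[use_alt] <- alt[use_alt]
    err_ppm <- (obs[best] - ref_mz) / ref_mz * 1e6
    ok <- abs(err_ppm) <= coarse_ppm
  } else {
    ok <- logical(0)
  }
  if (sum(ok) < min_matches) {
    message(sprintf(
      "recalibrate: only %d reference matches (< %d); calibration refused",
      sum(ok), min_matches))
    return(x)
  }
  mzc <- obs[best][ok]
  err <- err_ppm[ok]
  precal_rms <- sqrt(mean(err^2))
  fit <- if (degree == 0L) stats::lm(err ~ 1) else stats::lm(err ~ mzc)
  # trim mismatched calibrants (wrong coarse identifications) and refit
  for (pass in 1:2) {
    res <- stats::residuals(fit)
    cut <- max(3 * stats::mad(res), 0.05)
    keep <- abs(res) <= cut
    if (sum(keep) >= min_matches && any(!keep)) {
      mzc <- mzc[keep]; err <- err[keep]
      fit <- if (degree == 0L) stats::lm(err ~ 1) else stats::lm(err ~ mzc)
    }
  }
  pred_all <- stats::predict(fit, newdata = data.frame(mzc = x$peaks$mz))
  x$peaks$mz <- x$peaks$mz / (1 + pred_all * 1e-6)
  resid_rms <- sqrt(mean(stats::residuals(fit)^2))
  x$calibration <- "calibrated"
  x$calibration_rms_ppm <- resid_rms
  attr(x, "n_calibrants") <- sum(ok)
  attr(x, "precal_rms_ppm") <- precal_rms
  x
}
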