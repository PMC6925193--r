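# Per-sample FTICR-MS peak lists and the pre-assignment filters.

#' Construct a mass peak list
#'
#' One sample's centroided negative-mode peak list: m/z, intensity and
#' signal-to-noise per peak, with an optional charge annotation added by
#' [determine_charge()]. Peaks are stored strictly increasing in m/z;
#' duplicates closer than 1 ppb are collapsed to the more intense peak.
#'
#' @param mz Numeric m/z values (Da).
#' @param intensity Non-negative peak intensities (arbitrary units).
#' @param snr Signal-to-noise ratios (> 0).
#' @param sample_id Sample identifier string.
#' @param charge Optional integer charge per peak (NA until determined).
#' @param window Acquisition m/z window, default `c(200, 800)` Da.
#' @param calibration One of `"raw"` or `"calibrated"`.
#' @param calibration_rms_ppm Residual RMS of the internal calibration, ppm.
#' @return An object of class `mass_peaklist`: a list with elements
#'   `sample_id`, `peaks` (data.frame `mz,intensity,snr,charge,charge_src`),
#'   `window`, `calibration`, `calibration_rms_ppm`.
#' @export
mass_peaklist <- function(mz, intensity, snr, sample_id = "sample",
                          charge = NA_integer_, window = c(200, 800),
                          calibration = c("raw", "calibrated"),
                          calibration_rms_ppm = NA_real_) {
  calibration <- match.arg(calibration)
  stopifnot(length(mz) == length(intensity), length(mz) == length(snr))
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (any(snr <= 0)) stop("S/N must be positive")
  peaks <- data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity),
                      snr = as.numeric(snr),
                      charge = rep_len(as.integer(charge), length(mz)),
                      charge_src = rep_len(NA_character_, length(mz)))
  peaks <- peaks[order(peaks$mz, -peaks$intensity), , drop = FALSE]
  if (nrow(peaks) > 1L) {
    # collapse duplicates within 1 ppb; the more intense peak (sorted first
    # within a tie) is kept
    rel_ppb <- c(Inf, diff(peaks$mz) / peaks$mz[-1L] * 1e9)
    peaks <- peaks[rel_ppb > 1, , drop = FALSE]
  }
  rownames(peaks) <- NULL
  structure(list(sample_id = sample_id, peaks = peaks, window = window,
                 calibration = calibration,
                 calibration_rms_ppm = calibration_rms_ppm),
            class = "mass_peaklist")
}

#' @export
print.mass_peaklist <- function(x, ...) {
  cat(sprintf("<mass_peaklist> %s: %d peaks, m/z %.4f-%.4f, %s",
              x$sample_id, nrow(x$peaks),
              min(x$peaks$mz), max(x$peaks$mz), x$calibration))
  if (!is.na(x$calibration_rms_ppm)) {
    cat(sprintf(" (RMS %.3f ppm)", x$calibration_rms_ppm))
  }
  cat("\n")
  invisible(x)
}

#' Filter peaks by signal-to-noise and acquisition window
#'
#' Retains exactly the peaks with S/N strictly greater than `snr_min`
#' (default 6) whose m/z lies inside the acquisition window; order is
#' preserved. An empty result is allowed and raised as a warning.
#'
#' @param x A `mass_peaklist`.
#' @param snr_min S/N threshold; peaks must exceed it strictly.
#' @return A filtered `mass_peaklist`.
#' @export
filter_peaks <- function(x, snr_min = 6) {
  stopifnot(inherits(x, "mass_peaklist"))
  if (nrow(x$peaks) == 0L) stop("peak list is empty")
  keep <- x$peaks$snr > snr_min &
    x$peaks$mz >= x$window[1L] & x$peaks$mz <= x$window[2L]
  x$peaks <- x$peaks[keep, , drop = FALSE]
  rownames(x$peaks) <- NULL
  if (nrow(x$peaks) == 0L) warning("no peaks survive the S/N filter")
  x
}

#' Determine ion charge from 13C isotopologue spacing
#'
#' For each peak, looks for a satellite at +1.0033548/z (z = 1, 2, ...)
#' within a matching tolerance; the smallest spacing found fixes z. Peaks
#' with z > 1 are flagged for exclusion from formula assignment. Peaks with
#' no detectable satellite (and peaks that *are* satellites) default to the
#' majority charge of the abundant annotated peaks, with a `"defaulted"`
#' provenance flag. A total-mass-difference pass like this never implies a
#' fractional atom count because the spacing grid is the 13C mass defect
#' itself.
#'
#' @param x A `mass_peaklist`.
#' @param max_z Largest charge considered (default 2).
#' @param tol_mda Matching tolerance on the spacing, in mDa (default 2).
#' @return The peak list with `charge` and `charge_src`
#'   (`"satellite"`/`"defaulted"`) filled in.
#' @export
determine_charge <- function(x, max_z = 2L, tol_mda = 2) {
  stopifnot(inherits(x, "mass_peaklist"))
  pk <- x$peaks
  m <- pk$mz
  z <- rep(NA_integer_, length(m))
  tol <- tol_mda / 1000
  ord <- order(m)  # already sorted, but be safe
  ms <- m[ord]
  for (zz in seq_len(max_z)) {
    gap <- C13_MASS_DIFF / zz
    # for each peak, nearest peak to m + gap
    idx <- findInterval(ms + gap, ms)
    cand <- pmin(pmax(idx, 1L), length(ms))
    cand2 <- pmin(cand + 1L, length(ms))
    d1 <- abs(ms[cand] - (ms + gap))
    d2 <- abs(ms[cand2] - (ms + gap))
    hit <- pmin(d1, d2) <= tol
    z[ord][hit & is.na(z[ord])] <- zz
  }
  # satellites themselves: a peak that sits one 13C gap above an annotated
  # peak inherits that peak's charge but is not independent evidence
  maj <- {
    ann <- !is.na(z)
    if (any(ann)) {
      w <- tapply(pk$intensity[ann], z[ann], sum)
      as.integer(names(w)[which.max(w)])
    } else 1L
  }
  src <- ifelse(is.na(z), "defaulted", "satellite")
  z[is.na(z)] <- maj
  x$peaks$charge <- z
  x$peaks$charge_src <- src
  x
}

#' Drop multiply charged peaks
#'
#' Assignment assumes singly charged [M - H]^- ions; peaks annotated with
#' z != 1 are excluded (and counted).
#'
#' @param x A `mass_peaklist` after [determine_charge()].
#' @return The peak list restricted to z = 1, with attribute
#'   `n_excluded_multicharge`.
#' @export
drop_multicharged <- function(x) {
  stopifnot(inherits(x, "mass_peaklist"))
  keep <- is.na(x$peaks$charge) | x$peaks$charge == 1L
  n_excl <- sum(!keep)
  x$peaks <- x$peaks[keep, , drop = FALSE]
  rownames(x$peaks) <- NULL
  attr(x, "n_excluded_multicharge") <- n_excl
  x
}

#' Read / write peak lists
#'
#' Delimiter-separated text with a header row and columns `mz`, `intensity`,
#' `snr` (a `charge` column is written when present). Calibrated lists
#' round-trip bit-identically apart from the corrected m/z values.
#'
#' @param path File path.
#' @param sample_id Sample identifier (defaults to the file name).
#' @param sep Field separator, default tab.
#' @return `read_peaklist()` a `mass_peaklist`; `write_peaklist()` the path,
#'   invisibly.
#' @export
read_peaklist <- function(path, sample_id = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  req <- c("mz", "intensity", "snr")
  if (!all(req %in% names(df))) {
    stop("peak list must have columns mz, intensity, snr")
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  pl <- mass_peaklist(df$mz, df$intensity, df$snr, sample_id = sample_id)
  if ("charge" %in% names(df)) pl$peaks$charge <- as.integer(df$charge)
  pl
}

#' @rdname read_peaklist
#' @param x A `mass_peaklist`.
#' @export
write_peaklist <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "mass_peaklist"))
  df <- x$peaks[, c("mz", "intensity", "snr", "charge")]
  df$mz <- sprintf("%.7f", df$mz)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
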