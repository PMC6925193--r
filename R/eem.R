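# Excitation-emission matrices and 1D fluorescence descriptors.

#' Construct an excitation-emission matrix
#'
#' Fluorescence intensity on an emission x excitation grid (rows =
#' emission wavelengths, columns = excitation wavelengths). Scatter regions
#' are masked as NA, never clamped negative; other negative intensities
#' are truncated at zero.
#'
#' @param intensity Numeric matrix, emission rows x excitation columns.
#' @param ex Excitation grid, nm (default 280-410 in 10 nm steps).
#' @param em Emission grid, nm (default 300-700 in 5 nm steps).
#' @param sample_id Sample identifier.
#' @return An object of class `eem`.
#' @export
eem <- function(intensity, ex = seq(280, 410, by = 10),
                em = seq(300, 700, by = 5), sample_id = "sample") {
  intensity <- as.matrix(intensity)
  stopifnot(nrow(intensity) == length(em), ncol(intensity) == length(ex))
  if (is.unsorted(ex, strictly = TRUE) || is.unsorted(em, strictly = TRUE)) {
    stop("wavelength grids must be strictly increasing")
  }
  intensity[!is.na(intensity) & intensity < 0] <- 0
  dimnames(intensity) <- list(em = em, ex = ex)
  structure(list(intensity = intensity, ex = as.numeric(ex),
                 em = as.numeric(em), sample_id = sample_id),
            class = "eem")
}

#' Mask Rayleigh scatter bands
#'
#' Sets first-order (em = ex) and second-order (em = 2 ex) Rayleigh bands
#' to NA within +/- `width` nm; masked cells are treated as missing by the
#' trilinear fit.
#'
#' @param x An `eem`.
#' @param width Half-width of each masked band, nm (default 10).
#' @return The masked `eem`.
#' @export
mask_scatter <- function(x, width = 10) {
  stopifnot(inherits(x, "eem"))
  for (j in seq_along(x$ex)) {
    hit <- abs(x$em - x$ex[j]) <= width | abs(x$em - 2 * x$ex[j]) <= width
    x$intensity[hit, j] <- NA_real_
  }
  x
}

#' 1D fluorescence intensity-ratio descriptors
#'
#' Two scalar descriptors read off the EEM: the protein-like (tryptophan-
#' like) contribution F350/Fmax — emission at 350 nm over the maximum
#' emission intensity, both on the 280 nm excitation row — and the red-
#' shift asymmetry ratio F550/F375 — emission at 550 nm over 375 nm at
#' 350 nm excitation.
#'
#' @param x An `eem` covering excitation 280 and 350 nm and emission 350,
#'   375 and 550 nm.
#' @return Named numeric vector `f350_fmax`, `f550_f375`.
#' @export
fir_descriptors <- function(x) {
  stopifnot(inherits(x, "eem"))
  need_ex <- c(280, 350)
  need_em <- c(350, 375, 550)
  if (!all(need_ex %in% x$ex) || !all(need_em %in% x$em)) {
    stop("EEM grid must cover excitation 280/350 nm and emission 350/375/550 nm")
  }
  col280 <- x$intensity[, match(280, x$ex)]
  col350 <- x$intensity[, match(350, x$ex)]
  fmax <- max(col280, na.rm = TRUE)
  f350 <- col280[match(350, x$em)]
  f375 <- col350[match(375, x$em)]
  f550 <- col350[match(550, x$em)]
  if (!isTRUE(fmax > 0) || !isTRUE(f375 > 0)) {
    stop("zero denominator in fluorescence intensity ratio")
  }
  c(f350_fmax = unname(f350 / fmax), f550_f375 = unname(f550 / f375))
}

#' Read / write EEMs
#'
#' Matrix text: a header line of excitation wavelengths, then one row per
#' emission wavelength (`em` first column). Masked cells are written as NA.
#'
#' @param path File path.
#' @param sample_id Sample identifier (defaults to file name).
#' @return `read_eem()` an `eem`; `write_eem()` the path, invisibly.
#' @export
read_eem <- function(path, sample_id = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE)
  em <- df[[1L]]
  ex <- as.numeric(names(df)[-1L])
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  eem(as.matrix(df[, -1L, drop = FALSE]), ex = ex, em = em,
      sample_id = sample_id)
}

#' @rdname read_eem
#' @param x An `eem`.
#' @export
write_eem <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  df <- data.frame(em = x$em, x$intensity, check.names = FALSE)
  names(df) <- c("em", x$ex)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
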