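# CDOM absorption descriptors: Napierian absorption coefficients,
# exponential spectral slopes and the Helms slope ratio.

#' Construct an absorption spectrum
#'
#' UV-Vis optical density on a strictly increasing wavelength grid (1 nm
#' steps, 200-600 nm by convention) with the cuvette path length in metres.
#' Small negative optical densities (instrument noise) are tolerated down
#' to -0.005.
#'
#' @param wavelength Wavelength grid, nm.
#' @param od Optical density (absorbance), dimensionless.
#' @param path_length_m Cuvette path length in metres (default 0.01 = 1 cm).
#' @param sample_id Sample identifier.
#' @return An object of class `absorption_spectrum`.
#' @export
absorption_spectrum <- function(wavelength, od, path_length_m = 0.01,
                                sample_id = "sample") {
  stopifnot(length(wavelength) == length(od), path_length_m > 0)
  if (is.unsorted(wavelength, strictly = TRUE)) {
    stop("wavelength grid must be strictly increasing")
  }
  if (any(od < -0.005)) stop("optical density below noise floor (-0.005)")
  structure(list(wavelength = as.numeric(wavelength), od = as.numeric(od),
                 path_length_m = path_length_m, sample_id = sample_id),
            class = "absorption_spectrum")
}

#' Napierian absorption coefficient at a wavelength
#'
#' a_lambda = 2.303 A_lambda / L, with A the optical density and L the path
#' length in metres. The wavelength must sit on the measured grid;
#' interpolation is only performed when explicitly requested.
#'
#' @param spectrum An `absorption_spectrum`.
#' @param wavelength Wavelength(s), nm.
#' @param interpolate Allow linear interpolation off the grid.
#' @return Absorption coefficient(s), 1/m.
#' @export
absorption_coefficient <- function(spectrum, wavelength,
                                   interpolate = FALSE) {
  stopifnot(inherits(spectrum, "absorption_spectrum"))
  on_grid <- wavelength %in% spectrum$wavelength
  if (!all(on_grid) && !interpolate) {
    stop("wavelength off the measured grid; pass interpolate = TRUE")
  }
  a_all <- 2.303 * spectrum$od / spectrum$path_length_m
  stats::approx(spectrum$wavelength, a_all, xout = wavelength,
                rule = 1)$y
}

#' Exponential spectral slope over a wavelength range
#'
#' Fits a_lambda = a_ref exp(-S (lambda - lambda0)) by ordinary least
#' squares of ln(a) on lambda over the range; S is minus the fitted slope
#' and lambda0 the range start. Non-positive coefficients are dropped; at
#' least 10 usable grid points are required.
#'
#' @param spectrum An `absorption_spectrum`.
#' @param range Two-element nm interval, e.g. `c(275, 295)`.
#' @param nonlinear Refit by nonlinear least squares (starting from the
#'   log-linear estimate) for sensitivity analysis.
#' @return A list of class `slope_fit`: `s` (1/nm), `a_ref` (1/m at
#'   lambda0), `lambda0`, `fit_range`, `r_squared`, `n_points`.
#' @export
spectral_slope <- function(spectrum, range, nonlinear = FALSE) {
  stopifnot(inherits(spectrum, "absorption_spectrum"), length(range) == 2L)
  sel <- spectrum$wavelength >= range[1L] & spectrum$wavelength <= range[2L]
  lam <- spectrum$wavelength[sel]
  a <- 2.303 * spectrum$od[sel] / spectrum$path_length_m
  pos <- a > 0
  lam <- lam[pos]; a <- a[pos]
  if (length(a) < 10L) {
    stop("fewer than 10 positive absorption points in the fit range")
  }
  x <- lam - range[1L]
  fit <- stats::lm(log(a) ~ x)
  s <- -unname(stats::coef(fit)[2L])
  a_ref <- exp(unname(stats::coef(fit)[1L]))
  if (nonlinear) {
    nls_fit <- try(stats::nls(a ~ a0 * exp(-ss * x),
                              start = list(a0 = a_ref, ss = s)),
                   silent = TRUE)
    if (!inherits(nls_fit, "try-error")) {
      s <- unname(stats::coef(nls_fit)[["ss"]])
      a_ref <- unname(stats::coef(nls_fit)[["a0"]])
    }
  }
  ss_tot <- sum((log(a) - mean(log(a)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(s = s, a_ref = a_ref, lambda0 = range[1L],
                 fit_range = range, r_squared = r2, n_points = length(a)),
            class = "slope_fit")
}

#' Slope ratio Sr
#'
#' Ratio of the exponential slopes fitted over 275-295 nm and 350-400 nm;
#' inversely related to DOM molecular weight.
#'
#' @param spectrum An `absorption_spectrum`.
#' @return Dimensionless Sr.
#' @export
slope_ratio <- function(spectrum) {
  s1 <- spectral_slope(spectrum, c(275, 295))
  s2 <- spectral_slope(spectrum, c(350, 400))
  s1$s / s2$s
}

#' Carbon-specific absorbance
#'
#' Absorption at 254 nm normalised to organic carbon content (an efficient
#' extinction coefficient).
#'
#' @param a254 Absorption coefficient at 254 nm, 1/m.
#' @param c_org Organic carbon content, mM.
#' @return a254 / c_org, 1/m per mM.
#' @export
specific_absorbance <- function(a254, c_org) {
  if (any(c_org <= 0)) stop("c_org must be positive")
  a254 / c_org
}

#' Read / write absorption spectra
#'
#' Two-column delimited text (`wavelength_nm`, `od`) with a header; the
#' path length is carried in a `# path_length_m:` comment line.
#'
#' @param path File path.
#' @param sample_id Sample identifier (defaults to file name).
#' @return `read_absorption()` an `absorption_spectrum`;
#'   `write_absorption()` the path, invisibly.
#' @export
read_absorption <- function(path, sample_id = NULL) {
  first <- readLines(path, n = 5L)
  pl_line <- grep("^#\\s*path_length_m:", first, value = TRUE)
  pl <- if (length(pl_line)) as.numeric(sub(".*:", "", pl_line[1L])) else 0.01
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#")
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  absorption_spectrum(df$wavelength_nm, df$od, path_length_m = pl,
                      sample_id = sample_id)
}

#' @rdname read_absorption
#' @param x An `absorption_spectrum`.
#' @export
write_absorption <- function(x, path) {
  stopifnot(inherits(x, "absorption_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# path_length_m: %g", x$path_length_m), con)
  utils::write.table(data.frame(wavelength_nm = x$wavelength, od = x$od),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
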