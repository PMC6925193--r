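# Elemental formula arithmetic for CHNOS compositions.
#
# All masses are monoisotopic and come from the single table below; every
# mass computed anywhere in the package goes through monoisotopic_mass() so
# that assignment, calibration and the synthetic generator share one scale.

#' Monoisotopic isotope masses (Da)
#'
#' Fixed table of the lightest-isotope masses used throughout the package:
#' 12C (exactly 12 by definition), 1H, 14N, 16O, 32S, plus the 13C-12C mass
#' difference and the proton mass used for deprotonation.
#'
#' @format Named numeric vector.
#' @export
ISOTOPE_MASS <- c(
  C = 12.000000000,
  H = 1.007825032,
  N = 14.003074004,
  O = 15.994914620,
  S = 31.972071174
)

#' @rdname ISOTOPE_MASS
#' @export
PROTON_MASS <- 1.007276467

#' @rdname ISOTOPE_MASS
#' @export
C13_MASS_DIFF <- 1.003354838

#' Construct a molecular formula (or a table of them)
#'
#' A molecular formula is a CHNOS integer composition (phosphorus fixed at
#' zero throughout). The constructor is vectorised: passing equal-length
#' vectors gives a data.frame of formulae with the derived quantities
#' O/C, H/C, double-bond equivalents and neutral monoisotopic mass.
#'
#' @param c,h,n,o,s Non-negative integer atom counts; `c >= 1`.
#' @return A data.frame of class `molform_tbl` with columns `c`, `h`, `n`,
#'   `o`, `s`, `oc`, `hc`, `dbe`, `mass`.
#' @examples
#' molecular_formula(c = 16, h = 18, o = 9)
#' @export
molecular_formula <- function(c, h, n = 0L, o = 0L, s = 0L) {
  len <- max(length(c), length(h), length(n), length(o), length(s))
  c <- rep_len(as.integer(c), len)
  h <- rep_len(as.integer(h), len)
  n <- rep_len(as.integer(n), len)
  o <- rep_len(as.integer(o), len)
  s <- rep_len(as.integer(s), len)
  if (any(c < 1L)) stop("formula must contain at least one carbon")
  if (any(h < 0L | n < 0L | o < 0L | s < 0L)) {
    stop("atom counts must be non-negative")
  }
  out <- data.frame(c = c, h = h, n = n, o = o, s = s)
  out$oc <- o / c
  out$hc <- h / c
  out$dbe <- dbe_from_counts(c, h, n)
  out$mass <- monoisotopic_mass(out)
  class(out) <- c("molform_tbl", "data.frame")
  out
}

#' Neutral monoisotopic mass of a formula
#'
#' @param formula A `molform_tbl` (or any data.frame with columns
#'   `c,h,n,o,s`).
#' @return Monoisotopic mass in Da, one value per row.
#' @export
monoisotopic_mass <- function(formula) {
  with(formula,
       c * ISOTOPE_MASS[["C"]] + h * ISOTOPE_MASS[["H"]] +
       n * ISOTOPE_MASS[["N"]] + o * ISOTOPE_MASS[["O"]] +
       s * ISOTOPE_MASS[["S"]])
}

dbe_from_counts <- function(c, h, n) c + 1 - (h - n) / 2

#' Double-bond equivalents
#'
#' Rings-plus-double-bonds implied by a CHNOS(P = 0) composition:
#' DBE = C + 1 - (H - N - P)/2.
#'
#' @inheritParams monoisotopic_mass
#' @return DBE, a multiple of 0.5 (integer for even-electron neutral
#'   molecules with H - N even).
#' @export
dbe <- function(formula) dbe_from_counts(formula$c, formula$h, formula$n)

#' m/z of a deprotonated ion
#'
#' Negative electrospray ionisation produces even-electron [M - zH]^z- ions;
#' the observed m/z is the neutral mass minus z proton masses, divided by z.
#'
#' @inheritParams monoisotopic_mass
#' @param charge Positive integer charge (number of protons removed).
#' @return m/z in Da.
#' @export
mz_deprotonated <- function(formula, charge = 1L) {
  if (any(charge <= 0L)) stop("charge must be a positive integer")
  if (any(formula$h < charge)) {
    stop("formula must have at least `charge` exchangeable hydrogens")
  }
  (monoisotopic_mass(formula) - charge * PROTON_MASS) / charge
}

#' Heteroatom family of a formula
#'
#' Mutually exclusive, exhaustive composition families used for the
#' count-based contribution table: CHO (no N, no S), CHON (N only),
#' CHOS (S only), CHNOS (both).
#'
#' @inheritParams monoisotopic_mass
#' @return Character vector in `c("CHO","CHON","CHOS","CHNOS")`.
#' @export
heteroatom_family <- function(formula) {
  ifelse(formula$n > 0L,
         ifelse(formula$s > 0L, "CHNOS", "CHON"),
         ifelse(formula$s > 0L, "CHOS", "CHO"))
}

#' Canonical string key for a formula
#'
#' Formula identity throughout the package (set operations, joins across
#' samples) is the neutral CHNOS tuple; isomers are indistinct.
#'
#' @inheritParams monoisotopic_mass
#' @return Character vector like `"C16H18O9"`.
#' @export
formula_key <- function(formula) {
  if (nrow(formula) == 0L) return(character(0))
  paste0("C", formula$c, "H", formula$h,
         ifelse(formula$n > 0L, paste0("N", formula$n), ""),
         ifelse(formula$o > 0L, paste0("O", formula$o), ""),
         ifelse(formula$s > 0L, paste0("S", formula$s), ""))
}

#' Parse canonical formula keys back into a formula table
#'
#' Inverse of [formula_key()]; accepts keys in C/H/N/O/S order with counts
#' omitted only when zero (the order `formula_key()` emits).
#'
#' @param key Character vector of keys such as `"C16H18O9"`.
#' @return A `molform_tbl`.
#' @export
parse_formula_key <- function(key) {
  grab <- function(el) {
    m <- regmatches(key, regexec(paste0(el, "([0-9]+)"), key))
    vapply(m, function(x) if (length(x) == 2L) as.integer(x[2L]) else 0L, 1L)
  }
  molecular_formula(c = grab("C"), h = grab("H"), n = grab("N"),
                    o = grab("O"), s = grab("S"))
}
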