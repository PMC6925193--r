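# Spearman rank-correlation mapping of molecular abundances onto
# hydrochemistry gradients.

HYDRO_PARAMS <- c("temperature", "salinity", "ph", "alkalinity", "hco3",
                  "co2", "si", "c_org", "a254")

#' Validate a station hydrochemistry table
#'
#' One row per station: `station_id` plus temperature (degC), salinity
#' (g/kg), pH (NBS), total alkalinity and HCO3- and CO2 (umol/kg),
#' dissolved Si (uM), organic carbon (mM) and a254 (1/m).
#'
#' @param df A data.frame with `station_id` and the parameter columns.
#' @return The validated data.frame, classed `hydro_table`.
#' @export
hydro_table <- function(df) {
  miss <- setdiff(c("station_id", HYDRO_PARAMS), names(df))
  if (length(miss)) stop("missing hydrochemistry columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$station_id)) stop("duplicate station_id")
  if (any(df$ph <= 0 | df$ph >= 14)) stop("pH out of (0, 14)")
  neg <- c("alkalinity", "hco3", "co2", "si", "c_org", "a254", "salinity")
  for (p in neg) if (any(df[[p]] < 0)) stop("negative ", p)
  class(df) <- c("hydro_table", "data.frame")
  df
}

#' Read / write hydrochemistry tables
#'
#' Delimited text keyed by `station_id` with the standard parameter
#' columns.
#'
#' @param path File path.
#' @return `read_hydro()` a `hydro_table`; `write_hydro()` the path,
#'   invisibly.
#' @export
read_hydro <- function(path) {
  hydro_table(utils::read.table(path, header = TRUE, sep = "\t",
                                comment.char = "#",
                                stringsAsFactors = FALSE))
}

#' @rdname read_hydro
#' @param x A `hydro_table`.
#' @export
write_hydro <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.perm_null_cache <- new.env(parent = emptyenv())

spearman_null_rho <- function(n) {
  # exact permutation null of rho for tie-free ranks, cached per n
  key <- as.character(n)
  if (!is.null(.perm_null_cache[[key]])) return(.perm_null_cache[[key]])
  perms <- permutations_of(n)
  base <- seq_len(n)
  rho <- vapply(perms, function(p) stats::cor(base, p), 0)
  .perm_null_cache[[key]] <- rho
  rho
}

#' Two-sided p-value for a Spearman correlation
#'
#' t approximation `t = rho sqrt((n-2)/(1-rho^2))` on n - 2 degrees of
#' freedom for n >= 10; exact permutation null (all n! rank permutations)
#' for n < 10.
#'
#' @param rho Spearman correlation(s).
#' @param n Number of paired observations.
#' @return Two-sided p-value(s).
#' @export
spearman_pvalue <- function(rho, n) {
  if (n < 3L) stop("need at least 3 paired observations")
  if (n >= 10L) {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-15))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(rho) >= 1] <- 0
    pmin(p, 1)
  } else {
    null <- spearman_null_rho(n)
    vapply(rho, function(r) mean(abs(null) >= abs(r) - 1e-12), 0)
  }
}

#' Spearman correlation map of common-formula intensities vs hydrochemistry
#'
#' For every hydrochemistry parameter and every formula present in all
#' samples, the Spearman rank correlation (average-rank tie handling) of
#' the formula's sum-normalized intensity with the parameter across
#' stations, with a two-sided p-value and a significance flag at
#' `p < alpha`. Formulae or parameters that are constant across stations
#' have no defined rank correlation; those pairs are excluded and counted.
#'
#' @param samples List of `sample_ensemble` objects, one per station.
#' @param hydro A `hydro_table` with one row per station (matched 1:1 to
#'   the samples by station/sample id).
#' @param common Optional `molform_tbl` of formulae to test; default
#'   [common_formulae()] of the samples.
#' @param alpha Significance level (default 0.05).
#' @param exclude Station ids dropped before correlation (e.g. a known
#'   outlier station); default none.
#' @param parameters Hydrochemistry columns to test; default all nine.
#' @return A data.frame of class `correlation_map`: `parameter`, `key`,
#'   `oc`, `hc`, `r`, `p`, `significant`; attributes `n_stations`,
#'   `n_excluded_constant`, `alpha`.
#' @export
spearman_map <- function(samples, hydro, common = NULL, alpha = 0.05,
                         exclude = character(), parameters = HYDRO_PARAMS) {
  ids <- vapply(samples, function(s) attr(s, "sample_id"), "")
  keep <- !(ids %in% exclude)
  samples <- samples[keep]; ids <- ids[keep]
  hydro <- hydro[!(hydro$station_id %in% exclude), , drop = FALSE]
  if (!setequal(ids, hydro$station_id) || anyDuplicated(ids)) {
    stop("samples and hydrochemistry stations do not match 1:1")
  }
  n <- length(samples)
  if (n < 5L) stop("need at least 5 matched stations")
  hydro <- hydro[match(ids, hydro$station_id), , drop = FALSE]
  if (is.null(common)) common <- common_formulae(samples)
  if (nrow(common) == 0L) stop("no common formulae")
  ckeys <- formula_key(common)
  # stations x formulae intensity matrix
  M <- vapply(samples, function(s) {
    s$rel_intensity[match(ckeys, s$key)]
  }, numeric(length(ckeys)))
  M <- t(M)  # stations x formulae
  const_f <- apply(M, 2L, function(v) diff(range(v)) == 0)
  n_excl <- sum(const_f)
  Mr <- apply(M[, !const_f, drop = FALSE], 2L, rank)
  maps <- vector("list", length(parameters))
  for (pi in seq_along(parameters)) {
    pv <- hydro[[parameters[pi]]]
    if (diff(range(pv)) == 0) {
      n_excl <- n_excl + sum(!const_f)
      next
    }
    r <- as.numeric(stats::cor(rank(pv), Mr))
    p <- spearman_pvalue(r, n)
    maps[[pi]] <- data.frame(parameter = parameters[pi],
                             key = ckeys[!const_f],
                             oc = common$oc[!const_f],
                             hc = common$hc[!const_f],
                             r = r, p = p, significant = p < alpha)
  }
  out <- do.call(rbind, maps[!vapply(maps, is.null, TRUE)])
  rownames(out) <- NULL
  structure(out, class = c("correlation_map", "data.frame"),
            n_stations = n, n_excluded_constant = n_excl, alpha = alpha)
}

#' Select hydrochemistry parameters by significant-correlation count
#'
#' Parameters whose number of significant correlations with the common-
#' formula intensities strictly exceeds `min_significant` (default 200).
#'
#' @param map A `correlation_map`.
#' @param min_significant Count threshold (strict).
#' @return Character vector of selected parameter names.
#' @export
select_parameters <- function(map, min_significant = 200L) {
  stopifnot(inherits(map, "correlation_map"))
  counts <- tapply(map$significant, map$parameter, sum)
  names(counts)[counts > min_significant]
}

#' Van Krevelen overlay of correlation strengths
#'
#' One row per common formula with its Van Krevelen coordinates, the
#' correlation with `parameter`, and a highlight label by strict threshold:
#' `strong_pos` for r > `r_threshold`, `strong_neg` for r < -`r_threshold`,
#' otherwise `weak`.
#'
#' @param map A `correlation_map`.
#' @param parameter A parameter present in the map (normally one returned
#'   by [select_parameters()]).
#' @param r_threshold Highlight threshold (default 0.7).
#' @return A data.frame: `key`, `oc`, `hc`, `r`, `p`, `significant`,
#'   `highlight`.
#' @export
vk_overlay <- function(map, parameter, r_threshold = 0.7) {
  stopifnot(inherits(map, "correlation_map"))
  sub <- map[map$parameter == parameter, , drop = FALSE]
  if (nrow(sub) == 0L) stop("parameter not present in the correlation map")
  sub$highlight <- ifelse(sub$r > r_threshold, "strong_pos",
                          ifelse(sub$r < -r_threshold, "strong_neg", "weak"))
  rownames(sub) <- NULL
  sub[, c("key", "oc", "hc", "r", "p", "significant", "highlight")]
}

#' Hydrochemistry inter-correlation matrix
#'
#' Symmetric Spearman correlation matrix of the parameter columns across
#' stations (unit diagonal).
#'
#' @param hydro A `hydro_table` (>= 5 stations).
#' @param parameters Columns to include; default all nine.
#' @return Numeric parameter x parameter matrix.
#' @export
hydro_matrix <- function(hydro, parameters = HYDRO_PARAMS) {
  if (nrow(hydro) < 5L) stop("need at least 5 stations")
  stats::cor(as.matrix(hydro[, parameters]), method = "spearman")
}
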