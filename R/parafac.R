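# Nonnegative trilinear (PARAFAC) decomposition of EEM stacks.
#
# The model is X[i,j,k] ~ sum_r A[i,r] B[j,r] C[k,r] with nonnegative
# sample scores A, emission loadings B and excitation loadings C. Fitting
# is hierarchical alternating least squares (HALS: closed-form nonnegative
# column updates, objective non-increasing) with EM-style handling of the
# masked scatter cells: missing entries are imputed from the current model
# each sweep, so the observed-entry loss is also non-increasing.

khatri_rao <- function(U, V) {
  # rows ordered (u-row-major over V): result[(k-1)*nrow(V)+j, ] = U[k,]*V[j,]
  U[rep(seq_len(nrow(U)), each = nrow(V)), , drop = FALSE] *
    V[rep(seq_len(nrow(V)), times = nrow(U)), , drop = FALSE]
}

#' Tucker congruence between two loading vectors
#'
#' @param u,v Numeric vectors of equal length.
#' @return sum(u v) / sqrt(sum(u^2) sum(v^2)).
#' @export
tucker_congruence <- function(u, v) {
  sum(u * v) / sqrt(sum(u^2) * sum(v^2))
}

eem_tensor <- function(eems) {
  stopifnot(length(eems) >= 1L, all(vapply(eems, inherits, TRUE, "eem")))
  ex <- eems[[1L]]$ex; em <- eems[[1L]]$em
  same <- vapply(eems, function(e) identical(e$ex, ex) && identical(e$em, em),
                 TRUE)
  if (!all(same)) stop("all EEMs must share the same wavelength grids")
  X <- array(NA_real_, c(length(eems), length(em), length(ex)))
  for (i in seq_along(eems)) X[i, , ] <- eems[[i]]$intensity
  list(X = X, ex = ex, em = em,
       sample_id = vapply(eems, function(e) e$sample_id, ""))
}

hals_sweep <- function(Xu, A, G, P) {
  # one HALS pass over the columns of the mode factor A for unfolding Xu;
  # G = W'W, P = Xu W precomputed by the caller
  R <- ncol(A)
  for (r in seq_len(R)) {
    g <- G[r, r]
    if (g < 1e-12) { A[, r] <- 0; next }
    upd <- (P[, r] - A %*% G[, r] + A[, r] * g) / g
    A[, r] <- pmax(0, upd)
  }
  A
}

fit_trilinear_once <- function(X, R, max_iter, tol, rng_scale) {
  I <- dim(X)[1L]; J <- dim(X)[2L]; K <- dim(X)[3L]
  obs <- !is.na(X)
  Xc <- X
  Xc[!obs] <- mean(X[obs])
  A <- matrix(stats::runif(I * R, 0.1, 1) * rng_scale, I, R)
  B <- matrix(stats::runif(J * R, 0.1, 1), J, R)
  C <- matrix(stats::runif(K * R, 0.1, 1), K, R)
  sse_obs <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    X1 <- matrix(Xc, I, J * K)
    W <- khatri_rao(C, B); A <- hals_sweep(X1, A, crossprod(W), X1 %*% W)
    X2 <- matrix(aperm(Xc, c(2L, 1L, 3L)), J, I * K)
    W <- khatri_rao(C, A); B <- hals_sweep(X2, B, crossprod(W), X2 %*% W)
    X3 <- matrix(aperm(Xc, c(3L, 1L, 2L)), K, I * J)
    W <- khatri_rao(B, A); C <- hals_sweep(X3, C, crossprod(W), X3 %*% W)
    Xhat <- array(A %*% t(khatri_rao(C, B)), c(I, J, K))
    new_sse <- sum((X[obs] - Xhat[obs])^2)
    Xc[!obs] <- Xhat[!obs]
    trace <- c(trace, new_sse)
    if (is.finite(sse_obs) &&
        abs(sse_obs - new_sse) <= tol * max(sse_obs, 1e-300)) {
      sse_obs <- new_sse
      break
    }
    sse_obs <- new_sse
  }
  list(A = A, B = B, C = C, sse = sse_obs, trace = trace, iters = it)
}

#' Fit a nonnegative trilinear model to a stack of EEMs
#'
#' Alternating least squares with nonnegativity on all three modes,
#' multistart from random initialisations keeping the lowest reconstruction
#' error; convergence when the relative change in observed-entry error
#' falls below `tol` or `max_iter` sweeps. Emission and excitation loadings
#' are normalised to unit Euclidean norm (scale absorbed into the sample
#' scores) and components are ordered by ascending emission maximum, so
#' component 1 is the bluest (protein-like) component. Pairs of components
#' with inter-component congruence above 0.98 are flagged degenerate with a
#' warning.
#'
#' @param eems List of `eem` objects on a shared grid (>= 6 samples for a
#'   meaningful fit; fewer is refused).
#' @param n_components Number of trilinear components.
#' @param seed Integer seed for the random initialisations.
#' @param n_starts Number of random multistarts (default 10).
#' @param max_iter Maximum ALS sweeps per start (default 2500).
#' @param tol Relative convergence tolerance on the loss (default 1e-8).
#' @return An object of class `parafac_model`: `scores` (samples x R),
#'   `em_loadings`, `ex_loadings` (unit-norm columns), `em`, `ex`,
#'   `sample_id`, `variance_explained`, `sse`, `loss_trace`, `degenerate`.
#' @export
fit_trilinear <- function(eems, n_components, seed = 1L, n_starts = 10L,
                          max_iter = 2500L, tol = 1e-8) {
  if (length(eems) < 6L) stop("trilinear fit needs at least 6 samples")
  tens <- eem_tensor(eems)
  X <- tens$X
  obs <- !is.na(X)
  rng_scale <- stats::quantile(X[obs], 0.9)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- fit_trilinear_once(X, n_components, max_iter, tol, rng_scale)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  # normalise loadings, absorb scale into scores
  bn <- sqrt(colSums(best$B^2)); bn[bn == 0] <- 1
  cn <- sqrt(colSums(best$C^2)); cn[cn == 0] <- 1
  B <- sweep(best$B, 2L, bn, "/")
  C <- sweep(best$C, 2L, cn, "/")
  A <- sweep(best$A, 2L, bn * cn, "*")
  ord <- order(tens$em[apply(B, 2L, which.max)])
  A <- A[, ord, drop = FALSE]
  B <- B[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]
  sst <- sum((X[obs] - mean(X[obs]))^2)
  r2 <- 1 - best$sse / sst
  # degeneracy: triple-product congruence between component pairs
  degen <- FALSE
  R <- n_components
  if (R > 1L) {
    for (ca in seq_len(R - 1L)) for (cb in (ca + 1L):R) {
      cong <- tucker_congruence(B[, ca], B[, cb]) *
        tucker_congruence(C[, ca], C[, cb])
      if (abs(cong) > 0.98) degen <- TRUE
    }
    if (degen) warning("degenerate solution: inter-component congruence > 0.98")
  }
  structure(list(n_components = R, scores = A, em_loadings = B,
                 ex_loadings = C, em = tens$em, ex = tens$ex,
                 sample_id = tens$sample_id, variance_explained = r2,
                 sse = best$sse, loss_trace = best$trace,
                 iters = best$iters, degenerate = degen),
            class = "parafac_model")
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf("<parafac_model> %d components, %d samples, R2 = %.4f\n",
              x$n_components, nrow(x$scores), x$variance_explained))
  em_max <- x$em[apply(x$em_loadings, 2L, which.max)]
  ex_max <- x$ex[apply(x$ex_loadings, 2L, which.max)]
  for (r in seq_len(x$n_components)) {
    cat(sprintf("  C%d: ex %g / em %g nm\n", r, ex_max[r], em_max[r]))
  }
  invisible(x)
}

match_components <- function(B1, C1, B2, C2) {
  # best component permutation of model 2 onto model 1 by mean congruence
  R <- ncol(B1)
  perms <- permutations_of(R)
  best_p <- perms[[1L]]; best_v <- -Inf
  for (p in perms) {
    v <- mean(vapply(seq_len(R), function(r) {
      tucker_congruence(B1[, r], B2[, p[r]]) *
        tucker_congruence(C1[, r], C2[, p[r]])
    }, 0))
    if (v > best_v) { best_v <- v; best_p <- p }
  }
  best_p
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_of(n - 1L)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(n), i)[p])))
  }
  out
}

#' Per-component congruence between two trilinear models
#'
#' Matches components by the best permutation, then reports the emission x
#' excitation congruence product for each matched pair. Used for split-half
#' validation and for scoring recovery against ground-truth loadings.
#'
#' @param model A `parafac_model`.
#' @param em_ref,ex_ref Reference loading matrices (columns = components)
#'   on the same grids.
#' @return Numeric vector of per-component congruences.
#' @export
model_congruence <- function(model, em_ref, ex_ref) {
  stopifnot(inherits(model, "parafac_model"),
            ncol(em_ref) == model$n_components)
  p <- match_components(em_ref, ex_ref, model$em_loadings, model$ex_loadings)
  vapply(seq_len(model$n_components), function(r) {
    tucker_congruence(em_ref[, r], model$em_loadings[, p[r]]) *
      tucker_congruence(ex_ref[, r], model$ex_loadings[, p[r]])
  }, 0)
}

#' Choose the number of trilinear components
#'
#' Grows the model one component at a time over `candidate_range` and
#' accepts n while (a) the R-squared gain over n - 1 exceeds `delta_r2` and
#' (b) a split-half test passes: models fitted on two sample halves agree
#' in their emission/excitation loadings with per-component congruence
#' above `congruence_min`. The largest accepted n is returned; if no
#' candidate is accepted the range floor is returned with a warning.
#'
#' @param eems List of `eem` objects.
#' @param candidate_range Integer candidates within 2..7 (default 2:5).
#' @param seed Integer seed.
#' @param delta_r2 Minimum R-squared gain to accept another component
#'   (default 0.005, i.e. half a percentage point).
#' @param congruence_min Split-half congruence threshold (default 0.95).
#' @param n_starts,max_iter,tol Passed to [fit_trilinear()].
#' @return Integer: the selected number of components, with attributes
#'   `r_squared` (per candidate) and `split_half` (per candidate).
#' @export
select_components <- function(eems, candidate_range = 2:5, seed = 1L,
                              delta_r2 = 0.005, congruence_min = 0.95,
                              n_starts = 10L, max_iter = 2500L, tol = 1e-8) {
  stopifnot(min(candidate_range) >= 2L, max(candidate_range) <= 7L)
  candidate_range <- sort(unique(as.integer(candidate_range)))
  half1 <- seq_along(eems) %% 2L == 1L
  r2_prev <- fit_trilinear(eems, min(candidate_range) - 1L, seed = seed,
                           n_starts = n_starts, max_iter = max_iter,
                           tol = tol)$variance_explained
  r2_all <- sh_all <- stats::setNames(numeric(0), character(0))
  accepted <- integer(0)
  for (n in candidate_range) {
    full <- fit_trilinear(eems, n, seed = seed + n, n_starts = n_starts,
                          max_iter = max_iter, tol = tol)
    m1 <- fit_trilinear(eems[half1], n, seed = seed + 100L + n,
                        n_starts = n_starts, max_iter = max_iter, tol = tol)
    m2 <- fit_trilinear(eems[!half1], n, seed = seed + 200L + n,
                        n_starts = n_starts, max_iter = max_iter, tol = tol)
    sh <- min(model_congruence(m1, m2$em_loadings, m2$ex_loadings))
    gain <- full$variance_explained - r2_prev
    r2_all[as.character(n)] <- full$variance_explained
    sh_all[as.character(n)] <- sh
    if (gain > delta_r2 && sh > congruence_min) {
      accepted <- c(accepted, n)
      r2_prev <- full$variance_explained
    } else {
      break
    }
  }
  if (length(accepted) == 0L) {
    warning("no candidate passed the gain + split-half screen; ",
            "reporting the range floor")
    out <- min(candidate_range)
  } else {
    out <- max(accepted)
  }
  structure(out, r_squared = r2_all, split_half = sh_all)
}

#' Component score ratios
#'
#' Per-sample descriptors built from the scores of a 3-component model with
#' components ordered by ascending emission maximum (C1 ~ 350 nm
#' protein-like, C2 ~ 420 nm humic, C3 ~ 470 nm oxidized/red-shifted):
#' C2/C1, C2/(C1+C2), C2/(C1+C2+C3) and the protein-like contrast
#' C1/(C2+C3).
#'
#' @param model A 3-component `parafac_model`.
#' @return A data.frame: `sample_id`, `c2_c1`, `c2_c12`, `c2_c123`,
#'   `c1_c23`.
#' @export
component_ratios <- function(model) {
  stopifnot(inherits(model, "parafac_model"))
  if (model$n_components != 3L) stop("component ratios need a 3-component model")
  A <- model$scores
  if (any(A[, 1L] == 0) || any(A[, 1L] + A[, 2L] == 0) ||
      any(rowSums(A) == 0) || any(A[, 2L] + A[, 3L] == 0)) {
    stop("zero denominator in component ratio")
  }
  data.frame(sample_id = model$sample_id,
             c2_c1 = A[, 2L] / A[, 1L],
             c2_c12 = A[, 2L] / (A[, 1L] + A[, 2L]),
             c2_c123 = A[, 2L] / rowSums(A),
             c1_c23 = A[, 1L] / (A[, 2L] + A[, 3L]))
}
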