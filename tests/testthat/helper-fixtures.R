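# Shared fixtures and the independent assignment oracle.

# small transect used by unit tests (full-size runs live in the
# acceptance file)
small_design <- function(seed = 42L) {
  transect_design(n_stations = 6L, confluence_index = 3L,
                  shared_core = 300L, unique_per_south = 10L, seed = seed)
}

# Independent exhaustive oracle for the candidate search: per-mass
# arithmetic enumeration over N, S, C, O deriving the integer H interval
# from the tolerance window directly (no rounding, no shared code with the
# production binary-search path).
oracle_enumerate <- function(mz, tol_ppm, cons = atomic_constraints()) {
  mC <- 12; mH <- 1.007825032; mN <- 14.003074004
  mO <- 15.994914620; mS <- 31.972071174
  M <- mz + 1.007276467
  Mlo <- M * (1 - tol_ppm * 1e-6)
  Mhi <- M * (1 + tol_ppm * 1e-6)
  keys <- character(0)
  for (n in 0:cons$max_n) for (s in 0:cons$max_s) {
    for (cc in seq_len(cons$max_c)) {
      if (mC * cc + mN * n + mS * s + mO + mH > Mhi) break
      o_hi <- min(cons$o_range[2L], floor(cons$oc_max * cc))
      for (o in cons$o_range[1L]:o_hi) {
        base <- mC * cc + mN * n + mO * o + mS * s
        if (base + mH > Mhi) break
        h_lo <- max(ceiling((Mlo - base) / mH), 1)
        h_hi <- min(floor((Mhi - base) / mH), cons$max_h,
                    floor(cons$hc_max * cc))
        if (h_lo > h_hi) next
        for (h in h_lo:h_hi) {
          if ((h - n) %% 2L != 0L) next
          if (cc + 1 - (h - n) / 2 < 0) next
          keys <- c(keys, paste0(
            "C", cc, "H", h,
            if (n > 0L) paste0("N", n) else "",
            if (o > 0L) paste0("O", o) else "",
            if (s > 0L) paste0("S", s) else ""))
        }
      }
    }
  }
  sort(keys)
}

# a CHO CH2 homologous reference series spanning the window
cho_reference_series <- function(n = 20L) {
  molecular_formula(c = 9L + seq_len(n), h = 10L + 2L * seq_len(n),
                    o = rep(8L, n))
}

# a minimal parafac_model for ratio arithmetic tests
fake_model <- function(scores) {
  structure(list(n_components = 3L, scores = scores,
                 em_loadings = diag(3), ex_loadings = diag(3),
                 em = 1:3, ex = 1:3,
                 sample_id = paste0("S", seq_len(nrow(scores))),
                 variance_explained = 1, sse = 0,
                 loss_trace = 0, iters = 1L, degenerate = FALSE),
            class = "parafac_model")
}
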