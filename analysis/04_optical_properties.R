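#!/usr/bin/env Rscript
# Stage 4 — CDOM optics: absorption coefficients and exponential spectral
# slopes (275-295 and 350-400 nm windows, slope ratio Sr), 1D fluorescence
# intensity ratios (F350/Fmax at ex 280, F550/F375 at ex 350), trilinear
# (PARAFAC) decomposition of the EEM stack with data-driven choice of the
# component number, and the component score ratios.
#
# Writes results/optics.tsv, results/parafac_loadings.tsv and
# results/component_ratios.tsv.

suppressMessages(library(domtransect))

abs_files <- list.files("results/input", pattern = "^abs_",
                        full.names = TRUE)
spectra <- lapply(abs_files, function(f)
  read_absorption(f, sample_id = sub("^abs_", "",
                                     sub("\\.tsv$", "", basename(f)))))
optics <- do.call(rbind, lapply(spectra, function(sp) {
  data.frame(sample_id = sp$sample_id,
             a254 = absorption_coefficient(sp, 254),
             s_275_295 = spectral_slope(sp, c(275, 295))$s,
             s_350_400 = spectral_slope(sp, c(350, 400))$s,
             sr = slope_ratio(sp))
}))

eem_files <- list.files("results/input", pattern = "^eem_",
                        full.names = TRUE)
eems <- lapply(eem_files, function(f)
  read_eem(f, sample_id = sub("^eem_", "", sub("\\.tsv$", "", basename(f)))))
fir <- do.call(rbind, lapply(eems, function(e)
  as.data.frame(c(list(sample_id = e$sample_id),
                  as.list(fir_descriptors(e))))))
optics <- merge(optics, fir, by = "sample_id")
utils::write.table(cbind(optics[1], round(optics[-1], 4)),
                   "results/optics.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

n_comp <- select_components(eems, candidate_range = 2:4, seed = 1L,
                            n_starts = 4L)
cat(sprintf("component number selected: %d (R2 by n: %s)\n", n_comp,
            paste(sprintf("%s=%.4f", names(attr(n_comp, "r_squared")),
                          attr(n_comp, "r_squared")), collapse = ", ")))
model <- fit_trilinear(eems, as.integer(n_comp), seed = 1L, n_starts = 10L)
print(model)
loads <- data.frame(em = model$em, model$em_loadings)
names(loads) <- c("em_nm", paste0("C", seq_len(model$n_components), "_em"))
ex_loads <- data.frame(ex = model$ex, model$ex_loadings)
names(ex_loads) <- c("ex_nm", paste0("C", seq_len(model$n_components), "_ex"))
utils::write.table(round(loads, 5), "results/parafac_em_loadings.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(round(ex_loads, 5), "results/parafac_ex_loadings.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

ratios <- component_ratios(model)
utils::write.table(cbind(ratios[1], round(ratios[-1], 2)),
                   "results/component_ratios.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
half <- nrow(ratios) %/% 2
cat(sprintf("Sr: %.2f (southern half) vs %.2f (northern half)\n",
            mean(optics$sr[seq_len(half)]),
            mean(optics$sr[-seq_len(half)])))
cat(sprintf("protein-like contrast C1/(C2+C3): %.2f (south) -> %.2f (north)\n",
            mean(ratios$c1_c23[seq_len(half)]),
            mean(ratios$c1_c23[-seq_len(half)])))
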