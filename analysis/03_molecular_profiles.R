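#!/usr/bin/env Rscript
# Stage 3 — molecular profiling of the assigned ensembles: heteroatom
# family shares and number-averaged descriptors per station,
# intensity-weighted compound-class densities, the common (all-station)
# formula core and the near-unique formulae, and Van Krevelen tables.
#
# Writes the per-station descriptor and density tables under results/.

suppressMessages(library(domtransect))

files <- list.files("results/assignments", full.names = TRUE)
ensembles <- lapply(files, function(f) {
  a <- utils::read.table(f, header = TRUE, sep = "\t")
  sample_ensemble(molecular_formula(a$c, a$h, a$n, a$o, a$s), a$intensity,
                  sample_id = sub("\\.tsv$", "", basename(f)))
})

tab2 <- do.call(rbind, lapply(ensembles, number_averaged))
tab3 <- do.call(rbind, lapply(ensembles, class_densities))
utils::write.table(format(tab2, digits = 3),
                   "results/number_averaged.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cbind(tab3[1], round(tab3[-1], 3)),
                   "results/class_density.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

common <- common_formulae(ensembles)
uniq <- unique_formulae(ensembles)
utils::write.table(data.frame(key = formula_key(common),
                              mass = sprintf("%.6f", common$mass)),
                   "results/common_formulae.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
vk <- vk_table(ensembles[[1L]])
utils::write.table(vk, "results/vk_station01.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("stations: %d | common formulae: %d\n",
            length(ensembles), nrow(common)))
cat(sprintf("CHO share (count): %.1f-%.1f %% across stations\n",
            min(tab2$pct_cho), max(tab2$pct_cho)))
cat(sprintf("number-averaged O/C %.2f-%.2f, H/C %.2f-%.2f, DBE %.1f-%.1f\n",
            min(tab2$oc_n), max(tab2$oc_n), min(tab2$hc_n), max(tab2$hc_n),
            min(tab2$dbe_n), max(tab2$dbe_n)))
cat(sprintf("hydrolysable-tannin density: %.3f (first station) -> %.3f (last)\n",
            tab3$tannin_hydrolysable[1L],
            tab3$tannin_hydrolysable[nrow(tab3)]))
cat(sprintf("unique formulae in station 1: %d; in station %d: %d\n",
            nrow(uniq[[1L]]), length(uniq), nrow(uniq[[length(uniq)]])))
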