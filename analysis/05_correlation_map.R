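#!/usr/bin/env Rscript
# Stage 5 — correlation mapping: Spearman rank correlation of the
# sum-normalized intensities of the common (all-station) formulae against
# the station hydrochemistry, selection of parameters with > 200
# significant correlations (p < 0.05), Van Krevelen overlays highlighting
# |r| > 0.7, and the hydrochemistry inter-correlation matrix.
#
# Writes results/correlation_counts.tsv, results/vk_overlay_<param>.tsv
# and results/hydro_matrix.tsv.

suppressMessages(library(domtransect))

cfg <- read_pipeline_config("results/input/config.yml")
files <- list.files("results/assignments", full.names = TRUE)
ensembles <- lapply(files, function(f) {
  a <- utils::read.table(f, header = TRUE, sep = "\t")
  sample_ensemble(molecular_formula(a$c, a$h, a$n, a$o, a$s), a$intensity,
                  sample_id = sub("\\.tsv$", "", basename(f)))
})
hydro <- read_hydro("results/input/hydro.tsv")

map <- spearman_map(ensembles, hydro, alpha = cfg$alpha,
                    exclude = cfg$exclude)
counts <- sort(tapply(map$significant, map$parameter, sum),
               decreasing = TRUE)
utils::write.table(data.frame(parameter = names(counts),
                              n_significant = as.integer(counts)),
                   "results/correlation_counts.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("common formulae tested: %d over %d stations\n",
            length(unique(map$key)), attr(map, "n_stations")))
print(counts)

selected <- select_parameters(map, cfg$min_significant)
cat(sprintf("parameters with > %d significant correlations: %s\n",
            cfg$min_significant, paste(selected, collapse = ", ")))
for (p in selected) {
  ov <- vk_overlay(map, p, cfg$r_threshold)
  utils::write.table(cbind(ov[1:3], r = round(ov$r, 3),
                           p = signif(ov$p, 3),
                           ov[c("significant", "highlight")]),
                     sprintf("results/vk_overlay_%s.tsv", p),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  strong <- ov[ov$highlight != "weak", ]
  cat(sprintf("  %s: %d strong direct, %d strong inverse\n", p,
              sum(strong$highlight == "strong_pos"),
              sum(strong$highlight == "strong_neg")))
}

hm <- hydro_matrix(hydro[!(hydro$station_id %in% cfg$exclude), ,
                         drop = FALSE])
utils::write.table(round(hm, 3), "results/hydro_matrix.tsv",
                   sep = "\t", quote = FALSE, row.names = TRUE)
cat("strongly inter-correlated (|r| > 0.7) parameter pairs:\n")
idx <- which(abs(hm) > 0.7 & upper.tri(hm), arr.ind = TRUE)
for (k in seq_len(nrow(idx))) {
  cat(sprintf("  %s ~ %s: %.2f\n", rownames(hm)[idx[k, 1]],
              colnames(hm)[idx[k, 2]], hm[idx[k, 1], idx[k, 2]]))
}
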