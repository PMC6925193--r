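#!/usr/bin/env Rscript
# Stage 1 — simulate the study conditions: an 18-station south-to-north
# river transect with a 1,600-formula shared molecular core, planted
# singleton formulae in the southern stations, per-station FTICR peak
# lists (0.3 ppm noise + 1.5 ppm systematic offset), absorption spectra,
# EEMs from three fluorophores, and co-varying hydrochemistry.
#
# Writes the raw inputs (as the readers consume them) under results/input/.

suppressMessages(library(domtransect))

seed <- 1L
design <- transect_design(seed = seed)
sim <- simulate_transect(design)

dir.create("results/input", showWarnings = FALSE, recursive = TRUE)
for (pl in sim$peaklists) {
  write_peaklist(pl, sprintf("results/input/peaks_%s.tsv", pl$sample_id))
}
for (sp in sim$absorption) {
  write_absorption(sp, sprintf("results/input/abs_%s.tsv", sp$sample_id))
}
for (e in sim$eem$eems) {
  write_eem(e, sprintf("results/input/eem_%s.tsv", e$sample_id))
}
write_hydro(sim$hydro, "results/input/hydro.tsv")
write_pipeline_config(pipeline_config(seed = seed),
                      "results/input/config.yml")

dens <- sim$ensembles$truth$densities
south <- sim$ensembles$truth$regime == "south"
cat(sprintf("stations: %d (%d south / %d north of the confluence)\n",
            design$n_stations, sum(south), sum(!south)))
cat(sprintf("shared core: %d formulae; singletons per southern station: %d\n",
            design$shared_core, design$unique_per_south))
cat(sprintf("true hydrolysable-tannin density: %.3f (south) -> %.3f (north)\n",
            mean(dens$tannin_hydrolysable[south]),
            mean(dens$tannin_hydrolysable[!south])))
cat(sprintf("organic carbon: %.2f mM (south) -> %.2f mM (north)\n",
            mean(sim$hydro$c_org[south]), mean(sim$hydro$c_org[!south])))
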