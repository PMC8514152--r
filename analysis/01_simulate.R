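#!/usr/bin/env Rscript
# Stage 1 -- simulate the study's data landscape.
#
# Builds the default breed-structured scenario: a multi-breed high-density
# panel (20 breeds x 4 dogs) plus 40 breed-specific dogs, a 30-dog
# low-density study set of the focal breed (plus 8 overlap dogs genotyped
# at both densities), annotation dialects that disagree on strand for 5%
# of the low-density records, and a uniform 1 cM/Mb genetic map.
# Serializes everything as PED/MAP + annotation CSVs under
# results/simulated/.

library(panelpute)

seed <- 1L
cfg <- sim_config(seed = seed)
sc <- build_scenario(cfg)
write_scenario(sc, "results/simulated")

cat(sprintf("panel: %d dogs x %d sites (%d breeds + %d focal)\n",
            nrow(sc$panel_hd$genotypes), ncol(sc$panel_hd$genotypes),
            cfg$n_breeds, cfg$focal_panel_n))
cat(sprintf("study: %d dogs x %d low-density sites (%.0f%% of panel)\n",
            nrow(sc$study_ld$genotypes), ncol(sc$study_ld$genotypes),
            100 * cfg$ld_fraction))
cat(sprintf("injected strand flips: %d; overlap dogs: %d\n",
            length(sc$injected_flips), length(sc$overlap_ids)))
writeLines(sc$injected_flips, "results/simulated/injected_flips.txt")
cat("wrote results/simulated/\n")
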