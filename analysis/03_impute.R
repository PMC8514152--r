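#!/usr/bin/env Rscript
# Stage 3 -- hold-out, phasing and imputation.
#
# Eight overlap dogs (genotyped at both densities) are held out: they
# stay in the low-density study set and leave the reference panel.  The
# panel is phased with the iterative copying-model phaser (Ne = 200,
# nearest-neighbour conditioning), and the study set is imputed up to
# panel density in 2 Mb windows with 250 kb stitch buffers.

library(panelpute)

seed <- 1L
cfg <- sim_config(seed = seed)
sc <- build_scenario(cfg)              # source of overlap ids and truth

panel <- apply_annotation(
  read_pedmap("results/harmonized/panel.ped", "results/harmonized/panel.map"),
  read_annotation_csv("results/harmonized/panel_annot.csv"))
study <- read_pedmap("results/harmonized/study.ped",
                     "results/harmonized/study.map")
study <- apply_annotation(study, panel$sites)
map <- read_genetic_map("results/simulated/genetic_map.txt")

held <- panelpute:::with_seed(seed, sort(sample(sc$overlap_ids, 8L)))
panel <- subset_ds(panel, individuals = which(
  !panel$individuals$individual_id %in% held))
truth <- subset_ds(sc$panel_hd, individuals = held)

params <- model_params(phase_rounds_max = 3L)
panel <- chrom_rate_filter(panel, params$min_chrom_rate)$dataset
study <- chrom_rate_filter(study, params$min_chrom_rate)$dataset

cat(sprintf("phasing %d panel dogs at %d sites...\n",
            nrow(panel$genotypes), ncol(panel$genotypes)))
ref <- phase_reference(panel, map, params, seed = seed)
cat(sprintf("imputing %d study dogs up to %d sites...\n",
            nrow(study$genotypes), nrow(ref$sites)))
dres <- impute_dataset(study, ref, map, params)

dir.create("results/imputed", showWarnings = FALSE, recursive = TRUE)
write_gen_sample(dres, "results/imputed/study")
utils::write.table(
  data.frame(site_id = dres$sites$site_id, pos = dres$sites$pos,
             typed = as.integer(dres$typed),
             info = sprintf("%.6f", dres$info),
             theta_hat = sprintf("%.6f", dres$theta_hat)),
  "results/imputed/info.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(held, "results/imputed/held_ids.txt")
write_pedmap(truth, "results/imputed/truth.ped", "results/imputed/truth.map")
write_annotation_csv(truth$sites, "results/imputed/truth_annot.csv")
cat(sprintf("held dogs: %s\n", paste(held, collapse = " ")))
cat(sprintf("mean Info over imputed sites: %.3f\n",
            mean(dres$info[!dres$typed])))
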