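#!/usr/bin/env Rscript
# Stage 6 -- population structure of panel vs. study individuals.
#
# Identity-by-state distances over the sites shared by the harmonized
# panel and study set, embedded with classical multidimensional scaling.
# Checks that the focal-breed panel dogs cover the study dogs (no
# stratification between the genotyping platforms) and that breeds
# separate.

library(panelpute)

panel <- apply_annotation(
  read_pedmap("results/harmonized/panel.ped", "results/harmonized/panel.map"),
  read_annotation_csv("results/harmonized/panel_annot.csv"))
study <- apply_annotation(
  read_pedmap("results/harmonized/study.ped", "results/harmonized/study.map"),
  panel$sites)

study$individuals$individual_id <- paste0(study$individuals$individual_id,
                                          "_ld")
rownames(study$genotypes) <- study$individuals$individual_id
shared <- which(paste(panel$sites$chrom, panel$sites$pos) %in%
                paste(study$sites$chrom, study$sites$pos))
merged <- intersect_and_merge(list(subset_ds(panel, sites = shared), study),
                              source = "mds")$dataset
D <- ibs_distance_matrix(merged)
X <- mds_coordinates(D, 2)

pop <- merged$individuals$population
platform <- ifelse(grepl("_ld$", rownames(X)), "study_ld", "panel_hd")
focal <- startsWith(pop, "focal")
cent_hd <- colMeans(X[focal & platform == "panel_hd", , drop = FALSE])
cent_ld <- colMeans(X[focal & platform == "study_ld", , drop = FALSE])
cat(sprintf("focal-breed centroid distance between platforms: %.4f\n",
            sqrt(sum((cent_hd - cent_ld)^2))))
cat(sprintf("mean pairwise distance across all individuals: %.4f\n",
            mean(dist(X))))

dir.create("results/mds", showWarnings = FALSE, recursive = TRUE)
utils::write.table(
  data.frame(individual_id = rownames(X), population = pop,
             platform = platform, C1 = X[, 1], C2 = X[, 2]),
  "results/mds/coordinates.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("wrote results/mds/coordinates.tsv\n")
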