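#!/usr/bin/env Rscript
# Stage 2 -- read the serialized datasets back and harmonize them.
#
# Re-reads the PED/MAP files, reattaches the annotation dialects, decides
# strand orientation for every shared site (allele codes first, flanking
# sequence for palindromic pairs), applies the flips, and runs the QC
# cascades: panel individual call 0.95 / site call 0.97 / MAF 0.01; study
# individual call 0.95 / site call 0.97 / HWE 5e-5 / MAF 0.01.

library(panelpute)

inp <- "results/simulated"
panel <- apply_annotation(
  read_pedmap(file.path(inp, "panel.ped"), file.path(inp, "panel.map")),
  read_annotation_csv(file.path(inp, "hd_annot.csv")))
study <- apply_annotation(
  read_pedmap(file.path(inp, "study.ped"), file.path(inp, "study.map")),
  read_annotation_csv(file.path(inp, "ld_annot.csv")))

dec <- decide_strands(panel$sites, study$sites)
cat("strand decisions:\n"); print(table(dec$decision))
injected <- readLines(file.path(inp, "injected_flips.txt"))
detected <- dec$site_id[dec$decision == "flip"]
cat(sprintf("flips: %d detected, %d injected, %d false\n",
            length(detected), length(injected),
            sum(!detected %in% injected)))

aligned <- apply_strand_flips(study, dec)$dataset

qc_p <- qc_preset("final_panel")
panel <- filter_individuals(panel, qc_p$min_ind_call)$dataset
fsp <- filter_sites(panel, qc_p)
cat("panel site removals:\n"); print(fsp$report)
panel <- fsp$dataset

qc_s <- qc_preset("study")
aligned <- filter_individuals(aligned, qc_s$min_ind_call)$dataset
fss <- filter_sites(aligned, qc_s)
cat("study site removals:\n"); print(fss$report)
aligned <- fss$dataset
keep <- paste(aligned$sites$chrom, aligned$sites$pos) %in%
        paste(panel$sites$chrom, panel$sites$pos)
aligned <- subset_ds(aligned, sites = which(keep))

dir.create("results/harmonized", showWarnings = FALSE, recursive = TRUE)
write_pedmap(panel, "results/harmonized/panel.ped",
             "results/harmonized/panel.map")
write_annotation_csv(panel$sites, "results/harmonized/panel_annot.csv")
write_pedmap(aligned, "results/harmonized/study.ped",
             "results/harmonized/study.map")
cat(sprintf("harmonized panel %d x %d, study %d x %d\n",
            nrow(panel$genotypes), ncol(panel$genotypes),
            nrow(aligned$genotypes), ncol(aligned$genotypes)))
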