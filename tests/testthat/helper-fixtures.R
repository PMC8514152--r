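# Small fixtures built in code.

# A 2-individual, 3-site PED/MAP pair with one missing genotype.
write_tiny_pedmap <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ped <- c("fam1 ind1 0 0 0 -9 A A A G 0 0",
           "fam1 ind2 0 0 0 -9 A C G G T T")
  map <- c("1\ts1\t0\t100", "1\ts2\t0\t200", "1\ts3\t0\t300")
  ped_path <- file.path(dir, "tiny.ped")
  map_path <- file.path(dir, "tiny.map")
  writeLines(ped, ped_path)
  writeLines(map, map_path)
  list(ped = ped_path, map = map_path)
}

write_tiny_vcf <- function(path, records,
                           samples = c("s1", "s2")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

# Deterministic small genotype dataset.
toy_dataset <- function(n = 4, m = 6, seed = 1, missing = 0) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (missing > 0) g[sample(length(g), missing)] <- NA
  sites <- site_table(chrom = "1", pos = seq(100, by = 100, length.out = m),
                      allele_a = rep("A", m), allele_b = rep("G", m),
                      source = "toy")
  ind <- data.frame(individual_id = sprintf("ind%02d", seq_len(n)),
                    population = "toy", stringsAsFactors = FALSE)
  geno_dataset(sites, ind, g)
}

# Scaled-down scenario used by fast unit tests.
tiny_config <- function(seed = 7L, ...) {
  sim_config(n_sites = 300L, chrom_length_bp = 3e6, n_breeds = 4L,
             focal_size = 30L, focal_panel_n = 16L, focal_study_n = 10L,
             n_overlap = 6L, seed = seed, ...)
}
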