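test_that("ancestral pool is seed-deterministic and Beta-controlled", {
  cfg <- tiny_config(seed = 42L)
  a1 <- simulate_ancestral_pool(cfg)
  a2 <- simulate_ancestral_pool(cfg)
  expect_identical(a1$haplotypes, a2$haplotypes)
  expect_identical(a1$sites, a2$sites)
  expect_false(is.unsorted(a1$sites$pos, strictly = TRUE))

  # a tight Beta concentrates every frequency near 0.5
  cfg2 <- sim_config(n_sites = 200L, chrom_length_bp = 1e6,
                     n_ancestral = 500L, ancestral_maf_shape = c(1e6, 1e6),
                     seed = 1L)
  pool <- simulate_ancestral_pool(cfg2)
  f <- colMeans(pool$haplotypes)
  expect_true(all(abs(f - 0.5) < 0.01 + 3 * sqrt(0.25 / 1000)))

  cfg0 <- sim_config(n_sites = 0L, seed = 1L)
  empty <- simulate_ancestral_pool(cfg0)
  expect_equal(ncol(empty$haplotypes), 0L)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_sites = 100L, chrom_length_bp = 50), "more sites")
  expect_error(sim_config(founders_per_breed = 1L), "founders")
  expect_error(sim_config(flip_fraction = 1.5), "rates")
})

test_that("breed derivation conserves founder alleles without mutation", {
  cfg <- tiny_config(seed = 3L)
  pool <- simulate_ancestral_pool(cfg)
  map <- uniform_genetic_map(cfg$chrom_length_bp)
  # generations = 0: output haplotypes are a subset of ancestral rows
  b0 <- derive_breed(pool, 5L, 0L, map, mutation_rate = 0, seed = 2L)
  key <- function(h) apply(h, 1, paste, collapse = "")
  expect_true(all(key(b0$haplotypes) %in% key(pool$haplotypes)))
  # mosaicism conserves per-site alleles among those of the founders
  b <- derive_breed(pool, 5L, 6L, map, mutation_rate = 0, seed = 2L)
  f0 <- derive_breed(pool, 5L, 0L, map, mutation_rate = 0, seed = 2L)
  for (j in seq_len(ncol(b$haplotypes))) {
    expect_true(all(b$haplotypes[, j] %in% f0$haplotypes[, j]))
  }
  expect_error(derive_breed(pool, 10000L, 1L, map), "exceed")
})

test_that("breed bottlenecks create within-breed relatedness", {
  # mean pairwise identity within a small breed exceeds identity between
  # two independently derived breeds, averaged over seeds
  diffs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_sites = 150L, chrom_length_bp = 2e6,
                      n_ancestral = 60L, seed = 100L + s)
    pool <- simulate_ancestral_pool(cfg)
    map <- uniform_genetic_map(cfg$chrom_length_bp)
    b1 <- derive_breed(pool, 4L, 12L, map, 0, seed = 2 * s, breed = "b1")
    b2 <- derive_breed(pool, 4L, 12L, map, 0, seed = 2 * s + 1, breed = "b2")
    ident <- function(h1, h2) mean(h1 == h2)
    within <- mean(utils::combn(8, 2, FUN = function(ix)
      ident(b1$haplotypes[ix[1], ], b1$haplotypes[ix[2], ])))
    between <- mean(vapply(1:8, function(i)
      ident(b1$haplotypes[i, ], b2$haplotypes[i, ]), numeric(1)))
    within - between
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("genotyping error hits the configured rate", {
  cfg <- tiny_config(seed = 5L)
  pool <- simulate_ancestral_pool(cfg)
  map <- uniform_genetic_map(cfg$chrom_length_bp)
  breed <- derive_breed(pool, 20L, 4L, map, 0, seed = 9L)
  clean <- genotype_with_error(breed, 0)
  expect_identical(clean$genotypes, haps_to_genotypes(breed)$genotypes)
  all_err <- genotype_with_error(breed, 1, seed = 2L)
  expect_true(all(all_err$genotypes != clean$genotypes))
  some <- genotype_with_error(breed, 0.05, seed = 3L)
  n <- length(clean$genotypes)
  disc <- mean(some$genotypes != clean$genotypes)
  expect_lt(abs(disc - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("array design injects flips exactly as configured", {
  cfg <- tiny_config(seed = 11L)
  pool <- simulate_ancestral_pool(cfg)
  arr0 <- design_arrays(pool$sites, modifyList(cfg, list(flip_fraction = 0)),
                        seed = 1L)
  shared <- match(arr0$ld$site_id, arr0$hd$site_id)
  expect_equal(arr0$ld$allele_a, arr0$hd$allele_a[shared])
  expect_equal(arr0$ld$flank_up, arr0$hd$flank_up[shared])
  expect_length(arr0$flipped_ids, 0L)

  arr <- design_arrays(pool$sites, cfg, seed = 1L)
  shared <- match(arr$ld$site_id, arr$hd$site_id)
  flipped <- arr$ld$site_id %in% arr$flipped_ids
  pal <- arr$hd$allele_a[shared] == revcomp(arr$hd$allele_b[shared])
  # flipped non-palindromic: allele sets complement-equal but not equal
  fnp <- flipped & !pal
  expect_true(any(fnp))
  expect_true(all(arr$ld$allele_a[fnp] ==
                  revcomp(arr$hd$allele_a[shared][fnp])))
  expect_true(all(arr$ld$allele_a[fnp] != arr$hd$allele_a[shared][fnp]))
  # flipped palindromic: allele letters swap, flanks reveal the flip
  fp <- flipped & pal
  if (any(fp)) {
    expect_true(all(arr$ld$flank_up[fp] ==
                    revcomp(arr$hd$flank_down[shared][fp])))
  }
})

test_that("reverse complement on a hand-worked flank pair", {
  up <- "ACGTTTGGCA"; down <- "TTTACGCGAA"
  expect_equal(revcomp(down), "TTCGCGTAAA")
  expect_equal(revcomp(revcomp(up)), up)
  expect_error(revcomp("ACGX"), "non-DNA")
})

test_that("scenario assembly is internally consistent and deterministic", {
  cfg <- tiny_config(seed = 13L, genotyping_error_rate = 0)
  sc <- build_scenario(cfg)
  study_ids <- sc$study_ld$individuals$individual_id
  panel_ids <- sc$panel_hd$individuals$individual_id
  expect_true(all(sc$overlap_ids %in% study_ids))
  expect_true(all(sc$overlap_ids %in% panel_ids))
  # with zero genotyping error, overlap genotypes agree across densities
  hd_cols <- match(paste(sc$study_ld$sites$chrom, sc$study_ld$sites$pos),
                   paste(sc$panel_hd$sites$chrom, sc$panel_hd$sites$pos))
  for (id in sc$overlap_ids) {
    g_hd <- sc$panel_hd$genotypes[match(id, panel_ids), hd_cols]
    g_ld <- sc$study_ld$genotypes[match(id, study_ids), ]
    expect_equal(unname(g_ld), unname(g_hd))
  }
  # truth haplotype sums reproduce the error-free genotypes
  tr <- haps_to_genotypes(subset_haps(sc$truth_haplotypes, panel_ids))
  expect_identical(unname(tr$genotypes), unname(sc$panel_hd$genotypes))

  sc2 <- build_scenario(cfg)
  expect_identical(sc$panel_hd$genotypes, sc2$panel_hd$genotypes)
  expect_identical(sc$annotations, sc2$annotations)
})

test_that("allele-frequency spectrum is conserved by pure resampling", {
  cfg <- sim_config(n_sites = 200L, chrom_length_bp = 2e6, n_ancestral = 100L,
                    seed = 21L)
  pool <- simulate_ancestral_pool(cfg)
  map <- uniform_genetic_map(cfg$chrom_length_bp)
  b <- derive_breed(pool, 40L, 0L, map, mutation_rate = 0, seed = 4L)
  f_anc <- colMeans(pool$haplotypes)
  f_b <- colMeans(b$haplotypes)
  # founders are drawn without replacement: deviations are within
  # (hypergeometric <= binomial) sampling error
  se <- sqrt(f_anc * (1 - f_anc) / (2 * 40))
  expect_lt(mean(abs(f_b - f_anc)), mean(2.5 * se + 1e-6))
})

test_that("linkage disequilibrium decays with genetic distance", {
  trends <- vapply(1:20, function(s) {
    cfg <- sim_config(n_sites = 200L, chrom_length_bp = 10e6,
                      n_ancestral = 80L, seed = 300L + s)
    pool <- simulate_ancestral_pool(cfg)
    map <- uniform_genetic_map(cfg$chrom_length_bp)
    b <- derive_breed(pool, 20L, 15L, map, 0, seed = s)
    h <- b$haplotypes
    keep <- which(apply(h, 2, stats::var) > 0)
    h <- h[, keep]; cm <- interpolate_cm(map, b$sites$pos[keep])
    m <- ncol(h)
    pairs <- cbind(sample(m, 400, replace = TRUE),
                   sample(m, 400, replace = TRUE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    r2 <- vapply(seq_len(nrow(pairs)), function(i)
      stats::cor(h[, pairs[i, 1]], h[, pairs[i, 2]])^2, numeric(1))
    d <- abs(cm[pairs[, 1]] - cm[pairs[, 2]])
    stats::cor(d, r2, method = "spearman")
  }, numeric(1))
  expect_lt(mean(trends), 0)
  expect_gt(mean(trends < 0), 0.7)
})

test_that("scenario serialization is byte-stable under one seed", {
  cfg <- tiny_config(seed = 17L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(build_scenario(cfg), d1)
  write_scenario(build_scenario(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
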