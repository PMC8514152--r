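test_that("individual call-rate filter uses strict inequality", {
  ds <- toy_dataset(n = 3, m = 100, seed = 2)
  g <- ds$genotypes
  g[1, 1:11] <- NA     # 89/100 called -> removed at 0.90
  g[2, 1:10] <- NA     # 90/100 called -> kept at the boundary
  ds <- geno_dataset(ds$sites, ds$individuals, g)
  out <- filter_individuals(ds, 0.90)
  expect_equal(out$removed_ids, "ind01")
  expect_equal(nrow(out$dataset$genotypes), 2L)
  # zero-site dataset: call rate defined as 1, nobody removed
  empty <- subset_ds(ds, sites = integer(0))
  expect_length(filter_individuals(empty, 0.90)$removed_ids, 0L)
  expect_warning(filter_individuals(ds, 1.01), "all individuals removed")
})

test_that("site filters apply call rate, then HWE, then MAF, tallied once", {
  set.seed(4)
  n <- 100
  build_site <- function(counts) {
    rep(c(0L, 1L, 2L), counts)
  }
  g <- cbind(
    c(rep(0L, 50), rep(1L, 46), rep(NA, 4)),        # 96% called
    build_site(c(99, 1, 0)),                        # MAF 0.005
    build_site(c(50, 0, 50)),                       # HWE catastrophe
    build_site(c(25, 50, 25)),                      # clean
    build_site(c(40, 40, 20)))                      # clean-ish
  sites <- site_table("1", seq(100, by = 100, length.out = 5),
                      allele_a = "A", allele_b = "G")
  ds <- geno_dataset(sites, data.frame(individual_id = sprintf("i%03d", 1:n),
                                       population = "x"), g)
  out <- filter_sites(ds, qc_thresholds(0, 0.97, 5e-5, 0.01))
  expect_equal(unname(out$removed),
               c("call_rate", "maf", "hwe"))
  expect_equal(out$report$n_removed, c(1L, 1L, 1L))
  # removals partition: input = output + removed
  expect_equal(ncol(ds$genotypes),
               ncol(out$dataset$genotypes) + sum(out$report$n_removed))
  # monomorphic site with maf_min = 0 is kept (HWE p = 1)
  mono <- geno_dataset(sites[1, ],
                       data.frame(individual_id = c("a", "b"),
                                  population = "x"),
                       matrix(c(0L, 0L), 2, 1))
  kept <- filter_sites(mono, qc_thresholds(0, 0, 5e-5, 0))
  expect_equal(ncol(kept$dataset$genotypes), 1L)
})

test_that("allele pairs classify into same/flip/palindromic/mismatch", {
  rec <- function(a, b, pos = 100) {
    site_table("1", pos, allele_a = a, allele_b = b)
  }
  cls <- function(a, b) classify_allele_pair(a, b)$decision
  expect_equal(cls(rec("T", "C"), rec("A", "G")), "flip")
  expect_equal(cls(rec("A", "G"), rec("A", "G")), "same")
  expect_equal(cls(rec("A", "G"), rec("G", "A")), "same")     # set-equal
  expect_equal(cls(rec("A", "T"), rec("A", "T")), "ambiguous_palindromic")
  expect_equal(cls(rec("C", "G"), rec("G", "C")), "ambiguous_palindromic")
  expect_equal(cls(rec("A", "G"), rec("A", "C")), "mismatch")
  expect_equal(classify_allele_pair(rec("T", "C"), rec("A", "G"))$evidence,
               "alleles")
  expect_error(classify_allele_pair(rec("A", "G"), rec("A", "G", pos = 200)),
               "different positions")
})

test_that("flanking sequences resolve strand, including by hand-worked revcomp", {
  a <- site_table("1", 100, allele_a = "A", allele_b = "T",
                  flank_up = "ACGTTTGGCA", flank_down = "TTTACGCGAA")
  same <- a
  expect_equal(resolve_by_flanks(a, same, 10)$decision, "same")
  b <- a
  b$flank_up <- "TTCGCGTAAA"     # revcomp("TTTACGCGAA") by hand
  b$flank_down <- "TGCCAAACGT"   # revcomp("ACGTTTGGCA") by hand
  out <- resolve_by_flanks(a, b, 10)
  expect_equal(out$decision, "flip")
  expect_equal(out$evidence, "flanks")
  c <- a
  c$flank_up <- "ACGTTTGGCT"     # one mismatching base
  expect_equal(resolve_by_flanks(a, c, 10)$decision, "mismatch")
  short <- a; short$flank_up <- "ACG"
  expect_error(resolve_by_flanks(a, short, 10), "shorter")
})

test_that("strand flips are involutions and reports count them", {
  cfg <- tiny_config(seed = 19L)
  sc <- build_scenario(cfg)
  dec <- decide_strands(sc$annotations$hd, sc$study_ld$sites)
  out <- apply_strand_flips(sc$study_ld, dec)
  expect_equal(unname(out$report["flips_applied"]),
               length(sc$injected_flips))
  expect_equal(unname(out$report["excluded_mismatch"]), 0L)
  # flipping twice restores the original annotation
  dec_flip <- dec[dec$decision == "flip", ]
  twice <- apply_strand_flips(out$dataset, dec_flip)$dataset
  orig <- sc$study_ld
  expect_equal(twice$sites$allele_a, orig$sites$allele_a)
  expect_equal(twice$sites$flank_up, orig$sites$flank_up)
  # zero flips leave the dataset untouched
  none <- dec; none$decision <- "same"
  expect_identical(apply_strand_flips(sc$study_ld, none)$dataset$sites,
                   sc$study_ld$sites)
})

test_that("duplicate sites keep the best-called record with id tie-break", {
  base <- toy_dataset(n = 4, m = 3, seed = 6)
  s <- base$sites
  s$site_id <- c("dupB", "dupA", "solo")
  s$pos <- c(100L, 100L, 300L)
  g <- base$genotypes
  g[1:2, 1] <- NA                     # call rate 0.5 for dupB
  ds <- geno_dataset(s[order(s$pos), ], base$individuals, g)
  out <- dedup_sites(ds)
  expect_equal(out$n_removed, 1L)
  expect_true("dupA" %in% out$dataset$sites$site_id)   # higher call rate
  expect_false("dupB" %in% out$dataset$sites$site_id)

  tie <- geno_dataset(s, base$individuals, base$genotypes)
  out2 <- dedup_sites(tie)
  expect_true("dupA" %in% out2$dataset$sites$site_id)  # lexicographic tie
  clean <- dedup_sites(toy_dataset())
  expect_equal(clean$n_removed, 0L)
})

test_that("intersection merge aligns coding and is order-invariant", {
  mk <- function(pos, ids, b_allele, g, tag) {
    sites <- site_table("1", pos, allele_a = ifelse(b_allele == "G", "A", "G"),
                        allele_b = b_allele, source = tag)
    geno_dataset(sites, data.frame(individual_id = ids, population = tag), g)
  }
  d1 <- mk(c(100, 200, 300), c("a1", "a2"), rep("G", 3),
           matrix(c(0L, 1L, 2L, 1L, 0L, 2L), 2, 3), "d1")
  d2 <- mk(c(200, 300, 400), c("b1", "b2"), c("A", "G", "G"),
           matrix(c(1L, 0L, 0L, 2L, 1L, 1L), 2, 3), "d2")
  d3 <- mk(c(200, 300), c("c1", "c2"), c("G", "G"),
           matrix(c(2L, 1L, 0L, 0L), 2, 2), "d3")
  out <- intersect_and_merge(list(d1, d2, d3))
  expect_equal(out$dataset$sites$pos, c(200L, 300L))
  expect_equal(nrow(out$dataset$genotypes), 6L)
  # d2's first shared site had transposed coding: 0<->2 swapped
  expect_equal(unname(out$dataset$genotypes[3:4, 1]), c(1L, 2L))
  # frequency agreement after coding alignment
  perm <- intersect_and_merge(list(d3, d1, d2))
  expect_equal(perm$dataset$sites$pos, out$dataset$sites$pos)
  ord <- match(out$dataset$individuals$individual_id,
               perm$dataset$individuals$individual_id)
  expect_equal(unname(perm$dataset$genotypes[ord, ]),
               unname(out$dataset$genotypes))
  expect_error(intersect_and_merge(list(d1, d1)), "shared individual ids")

  # merging a dataset with a renamed copy of itself keeps frequencies
  d1b <- d1; d1b$individuals$individual_id <- c("z1", "z2")
  rownames(d1b$genotypes) <- c("z1", "z2")
  both <- intersect_and_merge(list(d1, d1b))$dataset
  expect_equal(unname(colMeans(both$genotypes)), unname(colMeans(d1$genotypes)))
})

test_that("conflicting allele sets are excluded with a report entry", {
  s1 <- site_table("1", c(100, 200), allele_a = c("A", "A"),
                   allele_b = c("G", "G"))
  s2 <- site_table("1", c(100, 200), allele_a = c("A", "A"),
                   allele_b = c("G", "C"))
  ind <- function(ids) data.frame(individual_id = ids, population = "x")
  d1 <- geno_dataset(s1, ind(c("a1")), matrix(c(1L, 2L), 1, 2))
  d2 <- geno_dataset(s2, ind(c("b1")), matrix(c(1L, 0L), 1, 2))
  out <- intersect_and_merge(list(d1, d2))
  expect_equal(out$dataset$sites$pos, 100L)
  expect_equal(out$report$excluded_conflict, 1L)
})
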