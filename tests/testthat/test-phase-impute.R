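test_that("model parameter invariants hold", {
  expect_error(model_params(ne = 0), "positive")
  expect_error(model_params(window_bp = 4e5, overlap_bp = 2e5), "window_bp")
  expect_error(model_params(theta = 1.5), "theta")
  expect_equal(miscopy_lambda(4), (1 / sum(1 / 1:3)) /
                 (2 * ((1 / sum(1 / 1:3)) + 4)))
})

test_that("switch probabilities follow the map-scaled closed form", {
  cm <- c(0, 0, 1, 1e6)
  s <- transition_weights(cm, ne = 200, K = 100)
  expect_equal(s[1], 0)                                   # zero distance
  expect_equal(s[2], 1 - exp(-4 * 200 * 0.01 / 100))      # d = 0.01 M
  expect_equal(s[3], 1, tolerance = 1e-9)                 # huge distance
  expect_error(transition_weights(c(1, 0), 200, 10), "map error")
})

test_that("per-chromosome rate filter removes failing individuals", {
  ds <- toy_dataset(n = 5, m = 10, seed = 8)
  g <- ds$genotypes
  g[3, 1:2] <- NA                       # 80% on this chromosome
  ds <- geno_dataset(ds$sites, ds$individuals, g)
  out <- chrom_rate_filter(ds, 0.90)
  expect_equal(out$removed_ids, "ind03")
  full <- chrom_rate_filter(toy_dataset(), 0.90)
  expect_length(full$removed_ids, 0L)
  # removing 3 of 585 leaves 582
  big <- toy_dataset(n = 585, m = 20, seed = 9)
  gb <- big$genotypes
  gb[c(10, 20, 30), 1:3] <- NA
  big <- geno_dataset(big$sites, big$individuals, gb)
  expect_equal(nrow(chrom_rate_filter(big, 0.90)$dataset$genotypes), 582L)
})

test_that("haploid forward-backward matches exhaustive path enumeration", {
  set.seed(31)
  for (rep in 1:12) {
    K <- sample(2:4, 1)
    M <- sample(3:5, 1)
    ref <- matrix(rbinom(K * M, 1, 0.5), K, M)
    cm <- sort(runif(M, 0, 2))
    n_typed <- sample(1:M, 1)
    typed <- sort(sample(M, n_typed))
    obs <- rbinom(n_typed, 1, 0.5)
    if (rep %% 4 == 0) obs[1] <- NA
    out <- impute_haploid(obs, typed, ref, cm, ne = 150)
    oracle <- oracle_haploid_posthoc(obs, typed, ref, cm, ne = 150)
    expect_equal(out$q, oracle$q, tolerance = 1e-10)
    # scaling-factor product equals the direct path sum
    expect_equal(out$loglik, log(oracle$lik), tolerance = 1e-10)
  }
})

test_that("haploid imputation handles degenerate references", {
  ref <- matrix(c(1L, 0L, 1L, 1L), 1, 4)
  cm <- c(0, 0.1, 0.2, 0.3)
  out <- impute_haploid(c(1L), 1L, ref, cm, ne = 200)
  lambda <- miscopy_lambda(1)
  expect_true(all(abs(out$q - ref[1, ]) <= lambda + 1e-12))
  expect_error(impute_haploid(1L, 1L, matrix(0L, 0, 4), cm), "empty reference")
  # no typed sites: posterior is the reference frequency
  ref2 <- rbind(c(1L, 0L), c(0L, 0L))
  out2 <- impute_haploid(integer(0), integer(0), ref2, c(0, 1))
  expect_equal(out2$q, c(0.5, 0))
})

test_that("a perfectly matching template dominates the posterior", {
  set.seed(77)
  K <- 6; M <- 30
  ref <- matrix(rbinom(K * M, 1, 0.5), K, M)
  cm <- seq(0, 0.5, length.out = M)       # tight linkage
  typed <- seq(1, M, by = 2)
  obs <- ref[3, typed]
  out <- impute_haploid(obs, typed, ref, cm, ne = 200)
  untyped <- setdiff(seq_len(M), typed)
  informative <- untyped[colMeans(ref[, untyped, drop = FALSE]) %in%
                           (seq_len(K - 1) / K)]
  agree <- abs(out$q[untyped] - ref[3, untyped])
  expect_gt(mean(1 - agree), 0.9)
})

test_that("diploid Viterbi attains the exhaustively enumerated optimum", {
  set.seed(53)
  for (rep in 1:10) {
    K <- sample(2:4, 1)
    M <- sample(3:5, 1)
    ref <- matrix(rbinom(K * M, 1, 0.5), K, M)
    cm <- sort(runif(M, 0, 3))
    g <- rbinom(M, 2, 0.5)
    if (rep %% 3 == 0) g[sample(M, 1)] <- NA
    ph <- phase_diploid(g, ref, cm, ne = 120)
    oracle <- oracle_diploid_viterbi(g, ref, cm, ne = 120)
    expect_equal(ph$score, oracle$score, tolerance = 1e-10)
    # the returned path itself achieves the optimum under the oracle scorer
    sc <- oracle_diploid_path_score(g, ref, cm, 120, ph$path[, 1], ph$path[, 2])
    expect_equal(sc, oracle$score, tolerance = 1e-10)
    # phasing consistency: pair sums reproduce the genotypes
    ok <- !is.na(g)
    expect_equal((ph$h1 + ph$h2)[ok], g[ok])
  }
})

test_that("phase is forced for homozygotes and tie-broken at lone het sites", {
  ref <- rbind(c(0L, 0L, 1L), c(0L, 1L, 1L))
  cm <- c(0, 0.5, 1)
  hom <- phase_diploid(c(0L, 2L, 2L), ref, cm)
  expect_equal(hom$h1, c(0L, 1L, 1L))
  expect_equal(hom$h2, c(0L, 1L, 1L))
  # single het site with agreeing templates: allele 1 to haplotype 1
  ref2 <- rbind(c(0L), c(0L))
  het <- phase_diploid(c(1L), ref2, 0)
  expect_equal(het$h1, 1L)
  expect_equal(het$h2, 0L)
})

test_that("reference phasing reproduces genotypes and is seed-stable", {
  cfg <- tiny_config(seed = 23L)
  sc <- build_scenario(cfg)
  panel <- subset_ds(sc$panel_hd, individuals = 1:20)
  params <- model_params(phase_states = 12L, phase_rounds_max = 3L)
  ref <- phase_reference(panel, sc$map, params, seed = 5L)
  n <- nrow(panel$genotypes)
  sums <- ref$haplotypes[seq(1, 2 * n, 2), ] + ref$haplotypes[seq(2, 2 * n, 2), ]
  ok <- !is.na(panel$genotypes)
  expect_true(all(sums[ok] == panel$genotypes[ok]))
  ref2 <- phase_reference(panel, sc$map, params, seed = 5L)
  expect_identical(ref$haplotypes, ref2$haplotypes)
})

test_that("probability triples are normalized and typed sites certain", {
  cfg <- tiny_config(seed = 29L)
  sc <- build_scenario(cfg)
  hd <- make_holdout(sc, 3L, "regenotyped_overlap", seed = 2L)
  params <- model_params(phase_states = 12L, phase_rounds_max = 2L)
  res <- run_imputation_study(hd$panel, hd$study, hd$truth, sc$map, params,
                              seed = 3L)
  dres <- res$dres
  ssum <- dres$p0 + dres$p1 + dres$p2
  expect_lt(max(abs(ssum - 1)), 1e-9)
  expect_true(all(dres$dosage >= 0 & dres$dosage <= 2))
  expect_true(all(dres$info <= 1 + 1e-9))
  # typed, unmasked sites carry the observed genotype as a one-hot triple
  typed_cols <- which(dres$typed)
  j <- typed_cols[1]
  expect_true(all(pmax(dres$p0[, j], dres$p1[, j], dres$p2[, j]) == 1))
})

test_that("imputing the reference individuals at full density is exact", {
  cfg <- tiny_config(seed = 37L, genotyping_error_rate = 0)
  sc <- build_scenario(cfg)
  ids <- sc$panel_hd$individuals$individual_id[1:6]
  truth_haps <- subset_haps(sc$truth_haplotypes, ids)
  study <- haps_to_genotypes(truth_haps)
  res <- impute_dataset(study, truth_haps, sc$map, model_params())
  expect_equal(unname(res$dosage), unname(study$genotypes), tolerance = 1e-9)
})

test_that("window stitching preserves the single-window computation", {
  # posterior probabilities cannot be bit-identical across window layouts
  # (the forward-backward correlation length at Ne = 200 spans megabases),
  # so the check is threefold: typed sites identical, bounded dosage drift
  # away from the cuts, and equal hold-out accuracy against truth
  cfg <- sim_config(n_sites = 400L, chrom_length_bp = 4e6, n_breeds = 4L,
                    focal_size = 30L, focal_panel_n = 16L, focal_study_n = 10L,
                    n_overlap = 6L, seed = 41L, genotyping_error_rate = 0)
  sc <- build_scenario(cfg)
  ref <- subset_haps(sc$truth_haplotypes,
                     sc$panel_hd$individuals$individual_id[1:20])
  study <- subset_ds(sc$study_ld, individuals = 1:4)
  study$sites <- sc$annotations$hd[match(study$sites$site_id,
                                         sc$annotations$hd$site_id), ]
  truth <- haps_to_genotypes(subset_haps(sc$truth_haplotypes,
                                         study$individuals$individual_id))
  one <- impute_dataset(study, ref, sc$map,
                        model_params(window_bp = 8e6, overlap_bp = 5e5))
  two <- impute_dataset(study, ref, sc$map,
                        model_params(window_bp = 2.2e6, overlap_bp = 5e5))
  typed <- which(one$typed)
  expect_identical(two$dosage[, typed], one$dosage[, typed])
  wins <- panelpute:::plan_windows(ref$sites$pos, 2.2e6, 5e5)
  cuts <- (wins$start[-1] + wins$end[-nrow(wins)]) / 2
  far <- vapply(ref$sites$pos, function(p) all(abs(p - cuts) >= 5e5),
                logical(1))
  expect_gt(sum(far), 100)
  expect_lt(mean(abs(two$dosage[, far] - one$dosage[, far])), 0.1)
  un <- !one$typed
  for (i in 1:4) {
    r_one <- dosage_r2(one$dosage[i, un], truth$genotypes[i, un])
    r_two <- dosage_r2(two$dosage[i, un], truth$genotypes[i, un])
    expect_lt(abs(r_one - r_two), 0.05)
  }
})

test_that("info score limits: certainty gives 1, the HWE prior gives 0", {
  n <- 50
  certain <- info_score(matrix(1, n, 1), matrix(0, n, 1), matrix(0, n, 1))
  expect_equal(certain$info, 1)
  mixed_idx <- cbind(matrix(0, n, 1), matrix(1, n, 1))  # all het, certain
  expect_equal(info_score(matrix(0, n, 1), matrix(1, n, 1),
                          matrix(0, n, 1))$info, 1)
  for (theta in c(0.05, 0.2, 0.5, 0.8)) {
    p0 <- matrix((1 - theta)^2, n, 1)
    p1 <- matrix(2 * theta * (1 - theta), n, 1)
    p2 <- matrix(theta^2, n, 1)
    out <- info_score(p0, p1, p2)
    expect_equal(out$info, 0, tolerance = 1e-12)
    expect_equal(out$theta_hat, theta, tolerance = 1e-12)
  }
  # monomorphic expectation by convention
  expect_equal(info_score(matrix(1, n, 1), matrix(0, n, 1),
                          matrix(0, n, 1))$theta_hat, 0)
  expect_equal(info_score(matrix(0, n, 1), matrix(0, n, 1),
                          matrix(1, n, 1))$info, 1)
})
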