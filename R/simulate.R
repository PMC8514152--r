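# Breed-structured haplotype/genotype simulator.
#
# A mosaic-pedigree model rather than a coalescent: an ancestral haplotype
# pool with Beta-distributed allele frequencies is bottlenecked into
# closed breeds that random-mate for a fixed number of non-overlapping
# generations, with map-scaled crossovers and per-site mutation.  This
# reproduces the structure the study design needs - within-breed
# relatedness, bottleneck LD, cosmopolitan diversity - without demographic
# realism.

#' Simulation configuration
#'
#' Defaults define the desk-scale study conditions used throughout the
#' package: one chromosome, a multi-breed panel of many breeds with few
#' dogs each, a breed-specific panel, and a low-density study set whose
#' site list is a 25% subset of the panel's.
#'
#' @param n_sites number of segregating sites.
#' @param chrom_length_bp chromosome length (bp).
#' @param chrom chromosome label.
#' @param n_ancestral ancestral pool size (individuals).
#' @param n_breeds number of non-focal breeds in the multi-breed panel.
#' @param founders_per_breed size of each non-focal breed (constant through
#'   the generations; >= 2).
#' @param generations generations of within-breed random mating.
#' @param focal_breed label of the breed the study set is drawn from.
#' @param focal_size focal-breed population size.
#' @param focal_panel_n focal-breed dogs genotyped at high density (panel).
#' @param focal_study_n focal-breed dogs genotyped at low density only.
#' @param n_overlap panel dogs re-genotyped at low density (hold-out pool).
#' @param ancestral_maf_shape Beta shape parameters for ancestral allele-1
#'   frequencies.
#' @param mutation_rate per-site per-meiosis allele-flip probability.
#' @param genotyping_error_rate probability a genotype call is replaced by
#'   a uniform draw from the other two genotypes.
#' @param ld_fraction fraction of sites on the low-density array.
#' @param flip_fraction fraction of low-density annotation records
#'   strand-flipped (reverse-complemented).
#' @param palindromic_fraction fraction of sites forced to allele pairs
#'   \{A,T\} or \{C,G\}.
#' @param rate_cm_per_mb uniform genetic-map rate.
#' @param seed integer seed fixing all randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sites = 2000L, chrom_length_bp = 20e6, chrom = "1",
                       n_ancestral = 200L,
                       n_breeds = 20L, founders_per_breed = 4L,
                       generations = 20L,
                       focal_breed = "focal", focal_size = 70L,
                       focal_panel_n = 40L, focal_study_n = 30L,
                       n_overlap = 8L,
                       ancestral_maf_shape = c(1, 1),
                       mutation_rate = 1e-5,
                       genotyping_error_rate = 0.002,
                       ld_fraction = 0.25,
                       flip_fraction = 0.05,
                       palindromic_fraction = 0.10,
                       rate_cm_per_mb = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(mutation_rate, genotyping_error_rate, ld_fraction,
             flip_fraction, palindromic_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates and fractions must lie in [0,1]")
  if (founders_per_breed < 2L) stop("founders_per_breed must be >= 2")
  if (n_sites > chrom_length_bp) stop("more sites than base pairs")
  if (focal_panel_n + focal_study_n > focal_size)
    stop("focal_size too small for panel + study split")
  if (n_overlap > focal_panel_n) stop("n_overlap exceeds focal panel size")
  structure(cfg, class = "sim_config")
}

#' Simulate the ancestral haplotype pool
#'
#' Per-site allele-1 frequencies are drawn from the configured Beta; sites
#' are placed uniformly (without replacement) on the chromosome, sorted.
#'
#' @param config a [sim_config()].
#' @return a [hap_set()] of `n_ancestral` individuals.
#' @export
simulate_ancestral_pool <- function(config) {
  with_seed(config$seed, {
    m <- as.integer(config$n_sites)
    if (m == 0L) {
      sites <- site_table(character(0), integer(0))
      return(hap_set(sites,
                     data.frame(individual_id = character(0),
                                population = character(0)),
                     matrix(integer(0), 0, 0)))
    }
    pos <- sort(sample.int(as.integer(config$chrom_length_bp), m))
    freq <- stats::rbeta(m, config$ancestral_maf_shape[1],
                         config$ancestral_maf_shape[2])
    n2 <- 2L * as.integer(config$n_ancestral)
    haps <- matrix(stats::rbinom(n2 * m, 1L, rep(freq, each = n2)), n2, m)
    alleles <- draw_allele_pairs(m, palindromic_fraction = 0)
    sites <- site_table(config$chrom, pos,
                        sprintf("s%05d", seq_len(m)),
                        alleles$a, alleles$b, source = "ancestral")
    ind <- data.frame(individual_id = sprintf("anc_%04d",
                                              seq_len(config$n_ancestral)),
                      population = "ancestral", stringsAsFactors = FALSE)
    attr(sites, "freq") <- freq
    hap_set(sites, ind, haps)
  })
}

# Random ordered allele pairs; a given fraction forced palindromic
# ({A,T} or {C,G}), the rest guaranteed non-complementary and distinct.
draw_allele_pairs <- function(m, palindromic_fraction) {
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  npal_pairs <- list(c("A", "C"), c("C", "A"), c("A", "G"), c("G", "A"),
                     c("C", "T"), c("T", "C"), c("G", "T"), c("T", "G"))
  is_pal <- stats::runif(m) < palindromic_fraction
  a <- b <- character(m)
  pick <- function(lst, k) lst[[k]]
  for (j in seq_len(m)) {
    p <- if (is_pal[j]) pick(pal_pairs, sample.int(4L, 1L))
         else pick(npal_pairs, sample.int(8L, 1L))
    a[j] <- p[1]; b[j] <- p[2]
  }
  list(a = a, b = b, palindromic = is_pal)
}

random_flanks <- function(m, k = 10L) {
  vapply(seq_len(m), function(i)
    paste(sample(BASES, k, replace = TRUE), collapse = ""), character(1))
}

#' Derive a breed from the ancestral pool
#'
#' Founder haplotypes are sampled without replacement; each generation,
#' every offspring receives one recombinant gamete from each of two
#' distinct parents.  Crossover counts are Poisson with mean equal to the
#' map length in Morgans; crossover positions are placed uniformly on the
#' genetic (cM) scale and mapped back to bp by inverse interpolation.
#' Mutation flips each transmitted allele independently.
#'
#' @param ancestral ancestral [hap_set()].
#' @param founders breed size (constant across generations).
#' @param generations number of non-overlapping generations.
#' @param map a `genetic_map`.
#' @param mutation_rate per-site per-meiosis flip probability.
#' @param seed integer seed.
#' @param breed breed label for individual ids.
#' @return a [hap_set()] of `founders` individuals.
#' @export
derive_breed <- function(ancestral, founders, generations, map,
                         mutation_rate = 0, seed = 1L, breed = "breed") {
  n_anc <- nrow(ancestral$individuals)
  if (founders > n_anc)
    stop("founders exceed available ancestral individuals")
  with_seed(seed, {
    m <- nrow(ancestral$sites)
    cm <- interpolate_cm(map, ancestral$sites$pos)
    total_cm <- max(interpolate_cm(map, map$pos))
    idx <- sample.int(n_anc, founders)
    hrows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    haps <- ancestral$haplotypes[hrows, , drop = FALSE]
    if (generations > 0L && m > 0L) {
      for (g in seq_len(generations)) {
        nxt <- matrix(0L, 2L * founders, m)
        for (i in seq_len(founders)) {
          par <- sample.int(founders, 2L)
          nxt[2L * i - 1L, ] <- make_gamete(haps, par[1], cm, total_cm,
                                            mutation_rate)
          nxt[2L * i, ] <- make_gamete(haps, par[2], cm, total_cm,
                                       mutation_rate)
        }
        haps <- nxt
      }
    }
    ind <- data.frame(individual_id = sprintf("%s_%03d", breed,
                                              seq_len(founders)),
                      population = breed, stringsAsFactors = FALSE)
    hap_set(ancestral$sites, ind, haps)
  })
}

# One recombinant gamete from parent i's two haplotypes.
make_gamete <- function(haps, i, cm, total_cm, mutation_rate) {
  h1 <- haps[2L * i - 1L, ]; h2 <- haps[2L * i, ]
  n_x <- stats::rpois(1L, total_cm / 100)
  start <- sample.int(2L, 1L)
  if (n_x == 0L) {
    g <- if (start == 1L) h1 else h2
  } else {
    x_cm <- sort(stats::runif(n_x, 0, total_cm))
    seg <- findInterval(cm, x_cm)            # 0..n_x
    use_h1 <- (seg + start) %% 2L == 1L
    g <- ifelse(use_h1, h1, h2)
  }
  if (mutation_rate > 0) {
    mut <- stats::runif(length(g)) < mutation_rate
    g[mut] <- 1L - g[mut]
  }
  g
}

#' Genotype haplotypes with array error
#'
#' Genotypes are haplotype-pair sums; with probability `error_rate` a call
#' is replaced by a uniform draw from the two other genotypes.
#'
#' @param haps a [hap_set()].
#' @param error_rate per-call error probability.
#' @param seed integer seed.
#' @return a `geno_ds`.
#' @export
genotype_with_error <- function(haps, error_rate = 0, seed = 1L) {
  ds <- haps_to_genotypes(haps)
  if (error_rate > 0) {
    with_seed(seed, {
      g <- ds$genotypes
      err <- matrix(stats::runif(length(g)) < error_rate, nrow(g), ncol(g))
      shift <- matrix(sample.int(2L, length(g), replace = TRUE),
                      nrow(g), ncol(g))
      g[err] <- (g[err] + shift[err]) %% 3L
      ds$genotypes <- g
    })
  }
  ds
}

#' Design high- and low-density array annotations
#'
#' The high-density annotation covers all sites on the true strand with
#' freshly drawn flanking sequences; the low-density annotation covers a
#' random `ld_fraction` subset, of which a `flip_fraction` are
#' reverse-complemented (alleles and flanks, with up/down flanks swapped),
#' emulating a platform annotated against the opposite strand.
#'
#' @param sites site table of all simulated sites.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `hd` and `ld` site tables, `ld_idx` (indices of
#'   low-density sites in `sites`), and `flipped_ids` (injected flips).
#' @export
design_arrays <- function(sites, config, seed = 1L) {
  with_seed(seed, {
    m <- nrow(sites)
    al <- draw_allele_pairs(m, config$palindromic_fraction)
    hd <- sites
    hd$allele_a <- al$a
    hd$allele_b <- al$b
    hd$flank_up <- random_flanks(m)
    hd$flank_down <- random_flanks(m)
    hd$source <- "hd_array"

    n_ld <- max(1L, round(config$ld_fraction * m))
    ld_idx <- sort(sample.int(m, n_ld))
    ld <- hd[ld_idx, , drop = FALSE]
    ld$source <- "ld_array"
    n_flip <- round(config$flip_fraction * n_ld)
    flip_local <- if (n_flip > 0L) sort(sample.int(n_ld, n_flip)) else integer(0)
    if (length(flip_local)) {
      fu <- ld$flank_up[flip_local]; fd <- ld$flank_down[flip_local]
      ld$allele_a[flip_local] <- complement_base(ld$allele_a[flip_local])
      ld$allele_b[flip_local] <- complement_base(ld$allele_b[flip_local])
      ld$flank_up[flip_local] <- revcomp(fd)
      ld$flank_down[flip_local] <- revcomp(fu)
    }
    rownames(hd) <- rownames(ld) <- NULL
    list(hd = hd, ld = ld, ld_idx = ld_idx,
         flipped_ids = ld$site_id[flip_local])
  })
}

#' Assemble a full synthetic scenario
#'
#' Builds the study design end-to-end: a multi-breed high-density panel
#' (few dogs from each non-focal breed) plus a breed-specific panel
#' component, a low-density focal-breed study set, overlap dogs genotyped
#' at both densities, dialect-differing annotations, truth haplotypes and
#' a genetic map.  Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `scenario` list: `panel_hd`, `study_ld`, `truth_haplotypes`,
#'   `overlap_ids`, `annotations`, `map`, `injected_flips`, `config`.
#' @export
build_scenario <- function(config) {
  pool <- simulate_ancestral_pool(config)
  map <- uniform_genetic_map(config$chrom_length_bp,
                             config$rate_cm_per_mb, config$chrom)
  breeds <- lapply(seq_len(config$n_breeds), function(b) {
    derive_breed(pool, config$founders_per_breed, config$generations, map,
                 config$mutation_rate, seed = derive_seed(config$seed, b),
                 breed = sprintf("breed%02d", b))
  })
  focal <- derive_breed(pool, config$focal_size, config$generations, map,
                        config$mutation_rate,
                        seed = derive_seed(config$seed, 998L),
                        breed = config$focal_breed)
  arrays <- design_arrays(pool$sites, config,
                          seed = derive_seed(config$seed, 999L))

  split <- with_seed(derive_seed(config$seed, 997L), {
    perm <- sample.int(config$focal_size)
    panel_i <- sort(perm[seq_len(config$focal_panel_n)])
    study_i <- sort(perm[config$focal_panel_n + seq_len(config$focal_study_n)])
    overlap_i <- sort(sample(panel_i, config$n_overlap))
    list(panel = panel_i, study = study_i, overlap = overlap_i)
  })
  focal_ids <- focal$individuals$individual_id

  all_haps <- bind_hapsets(c(breeds, list(focal)))
  all_haps$sites <- arrays$hd     # truth lives on the true (HD) strand
  panel_ids <- c(unlist(lapply(breeds, function(b) b$individuals$individual_id)),
                 focal_ids[split$panel])
  panel_haps <- subset_haps(all_haps, panel_ids)
  panel_hd <- genotype_with_error(panel_haps, config$genotyping_error_rate,
                                  seed = derive_seed(config$seed, 600L))
  panel_hd$sites <- arrays$hd

  study_ids <- c(focal_ids[split$study], focal_ids[split$overlap])
  study_haps <- subset_haps(all_haps, study_ids)
  study_full <- genotype_with_error(study_haps, config$genotyping_error_rate,
                                    seed = derive_seed(config$seed, 700L))
  study_ld <- subset_ds(study_full, sites = arrays$ld_idx)
  study_ld$sites <- arrays$ld     # low-density dialect (flips injected)

  structure(list(panel_hd = panel_hd,
                 study_ld = study_ld,
                 truth_haplotypes = all_haps,
                 overlap_ids = focal_ids[split$overlap],
                 annotations = list(hd = arrays$hd, ld = arrays$ld),
                 map = map,
                 injected_flips = arrays$flipped_ids,
                 config = config),
            class = "scenario")
}

# Stack haplotype sets sharing one site table.
bind_hapsets <- function(sets) {
  sites <- sets[[1]]$sites
  ind <- do.call(rbind, lapply(sets, `[[`, "individuals"))
  haps <- do.call(rbind, lapply(sets, `[[`, "haplotypes"))
  hap_set(sites, ind, haps)
}

#' Serialize a scenario to standard formats
#'
#' Writes PED/MAP for the panel and study set, annotation CSVs and the
#' genetic map, so synthetic and real data enter the pipeline identically.
#'
#' @param scenario a [build_scenario()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedmap(scenario$panel_hd, file.path(dir, "panel.ped"),
               file.path(dir, "panel.map"))
  write_pedmap(scenario$study_ld, file.path(dir, "study.ped"),
               file.path(dir, "study.map"))
  write_annotation_csv(scenario$annotations$hd, file.path(dir, "hd_annot.csv"))
  write_annotation_csv(scenario$annotations$ld, file.path(dir, "ld_annot.csv"))
  utils::write.table(scenario$map[, c("pos", "rate", "cum")],
                     file.path(dir, "genetic_map.txt"),
                     row.names = FALSE, col.names = c("pos", "rate_cM_Mb", "cM"),
                     quote = FALSE)
  invisible(dir)
}
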