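# Accuracy assessment: hold-out construction, dosage R-squared, hard-call
# concordance, and Info/frequency stratification.

#' Build a hold-out design from a scenario
#'
#' `regenotyped_overlap`: held dogs were genotyped on both arrays; they
#' stay in the low-density study set and are removed from the panel, and
#' truth is their (error-bearing) high-density array genotypes.
#' `artificial_lowdensity`: held dogs come from the high-density panel;
#' their genotypes are down-filtered to the low-density site list and
#' appended to the study set, and truth is the same high-density calls.
#'
#' @param scenario a [build_scenario()] result.
#' @param n_held number of held dogs (default 8).
#' @param mode hold-out mode.
#' @param seed integer seed for the random selection.
#' @return list: `study` (a `geno_ds`), `panel` (a `geno_ds` without the
#'   held dogs), `truth` (held dogs' high-density `geno_ds`), `held_ids`.
#' @export
make_holdout <- function(scenario, n_held = 8L,
                         mode = c("regenotyped_overlap",
                                  "artificial_lowdensity"),
                         seed = 1L) {
  mode <- match.arg(mode)
  panel <- scenario$panel_hd
  if (mode == "regenotyped_overlap") {
    pool <- scenario$overlap_ids
    if (length(pool) < n_held) stop("not enough overlap individuals")
    held <- with_seed(seed, sort(sample(pool, n_held)))
    study <- scenario$study_ld
  } else {
    focal <- scenario$config$focal_breed
    pool <- setdiff(panel$individuals$individual_id[
                      panel$individuals$population == focal],
                    scenario$overlap_ids)
    if (length(pool) < n_held) stop("not enough panel focal-breed individuals")
    held <- with_seed(seed, sort(sample(pool, n_held)))
    ld_key <- paste(scenario$study_ld$sites$chrom, scenario$study_ld$sites$pos)
    hd_key <- paste(panel$sites$chrom, panel$sites$pos)
    ld_cols <- match(ld_key, hd_key)
    held_ld <- subset_ds(subset_ds(panel, individuals = held),
                         sites = ld_cols)
    held_ld$sites <- scenario$study_ld$sites  # low-density dialect
    study <- intersect_and_merge(list(scenario$study_ld, held_ld),
                                 source = "study+held")$dataset
  }
  keep <- setdiff(panel$individuals$individual_id, held)
  truth <- subset_ds(panel, individuals = held)
  list(study = study, panel = subset_ds(panel, individuals = keep),
       truth = truth, held_ids = held, mode = mode)
}

#' Dosage R-squared against truth genotypes
#'
#' Squared Pearson correlation of imputed dosage and truth genotype over
#' the masked (imputed) sites only; observed sites are excluded from
#' scoring.  Undefined (zero truth variance or fewer than two sites)
#' gives `NA` with a warning.
#'
#' @param dosage numeric vector of dosages.
#' @param truth genotype vector (0/1/2/NA); missing truth is skipped.
#' @return R-squared in `[0, 1]`, or `NA`.
#' @export
dosage_r2 <- function(dosage, truth) {
  ok <- !is.na(truth) & !is.na(dosage)
  if (sum(ok) < 2L || stats::var(truth[ok]) == 0) {
    warning("R-squared undefined: fewer than 2 sites or zero truth variance")
    return(NA_real_)
  }
  stats::cor(dosage[ok], truth[ok])^2
}

#' Hard-call genotypes from probability triples
#'
#' Uncertainty is `1 - max(triple)`; calls with uncertainty above the
#' threshold become missing, otherwise the argmax genotype is returned.
#'
#' @param p0,p1,p2 probability matrices or vectors.
#' @param uncertainty_max maximum allowed uncertainty (default 0.1).
#' @return integer matrix/vector of genotypes with `NA` for no-calls.
#' @export
hard_call <- function(p0, p1, p2, uncertainty_max = 0.1) {
  pm <- pmax(p0, p1, p2)
  call <- ifelse(p0 >= p1 & p0 >= p2, 0L, ifelse(p1 >= p2, 1L, 2L))
  call[1 - pm > uncertainty_max] <- NA_integer_
  call
}

#' Genotype concordance
#'
#' Percent of non-missing hard calls matching non-missing truth; missing
#' calls are excluded from numerator and denominator, with the missing
#' fraction reported separately.
#'
#' @param calls hard-called genotypes (NA = no-call).
#' @param truth truth genotypes (NA skipped).
#' @return list: `percent` (NA if nothing comparable), `n_compared`,
#'   `n_match`, `missing_fraction` (no-calls among sites with truth).
#' @export
concordance <- function(calls, truth) {
  has_truth <- !is.na(truth)
  comp <- has_truth & !is.na(calls)
  n_comp <- sum(comp)
  n_match <- sum(calls[comp] == truth[comp])
  list(percent = if (n_comp > 0L) 100 * n_match / n_comp else NA_real_,
       n_compared = n_comp, n_match = n_match,
       missing_fraction = if (any(has_truth))
         mean(is.na(calls[has_truth])) else NA_real_)
}

#' Evaluate imputation accuracy for held individuals
#'
#' @param dres a `dosage_result` for the study set (held dogs included).
#' @param truth a `geno_ds` of the held dogs' high-density genotypes.
#' @param uncertainty_max hard-call threshold.
#' @return list: `per_individual` (R2, concordance, missing fraction),
#'   `mean_r2`, `concordance_pct` (overall), `masked_idx`, plus matrices
#'   `calls` and aligned `truth` over masked sites.
#' @export
evaluate_holdout <- function(dres, truth, uncertainty_max = 0.1) {
  ids <- truth$individuals$individual_id
  rows <- match(ids, dres$individuals$individual_id)
  if (anyNA(rows)) stop("held individuals missing from dosage result")
  key_d <- paste(dres$sites$chrom, dres$sites$pos)
  key_t <- paste(truth$sites$chrom, truth$sites$pos)
  cols_t <- match(key_d, key_t)          # truth columns for each dosage site
  masked <- which(!dres$typed & !is.na(cols_t))
  Tm <- truth$genotypes[, cols_t[masked], drop = FALSE]
  D <- dres$dosage[rows, masked, drop = FALSE]
  calls <- hard_call(dres$p0[rows, masked, drop = FALSE],
                     dres$p1[rows, masked, drop = FALSE],
                     dres$p2[rows, masked, drop = FALSE],
                     uncertainty_max)
  per <- data.frame(individual_id = ids,
                    r2 = NA_real_, concordance_pct = NA_real_,
                    missing_fraction = NA_real_)
  for (i in seq_along(ids)) {
    per$r2[i] <- dosage_r2(D[i, ], Tm[i, ])
    cc <- concordance(calls[i, ], Tm[i, ])
    per$concordance_pct[i] <- cc$percent
    per$missing_fraction[i] <- cc$missing_fraction
  }
  overall <- concordance(as.vector(calls), as.vector(Tm))
  list(per_individual = per,
       mean_r2 = mean(per$r2, na.rm = TRUE),
       concordance_pct = overall$percent,
       masked_idx = masked, calls = calls, truth = Tm)
}

#' Stratify accuracy by Info score
#'
#' Ten bins `[0,0.1), ..., [0.9,1.0]` (boundaries go up; scores below 0
#' clamp into the first bin).  Per bin: share of all imputed calls,
#' concordance among truth-heterozygous and truth-homozygous genotypes,
#' mean expected allele-1 frequency, and the count of sites with expected
#' frequency below 0.05.
#'
#' @param dres a `dosage_result` with `info` and `theta_hat`.
#' @param eval_res result of [evaluate_holdout()] (supplies calls/truth
#'   over the masked sites).
#' @return data.frame with one row per Info bin.
#' @export
stratify_by_info <- function(dres, eval_res) {
  masked <- eval_res$masked_idx
  info <- pmin(pmax(dres$info[masked], 0), 1)
  bin <- pmin(floor(info * 10) + 1L, 10L)
  theta <- dres$theta_hat[masked]
  calls <- eval_res$calls; truth <- eval_res$truth
  n_calls_total <- sum(!is.na(calls))
  out <- data.frame(bin = seq_len(10L),
                    lower = seq(0, 0.9, by = 0.1),
                    upper = seq(0.1, 1, by = 0.1),
                    share_pct = 0, het_concordance_pct = NA_real_,
                    hom_concordance_pct = NA_real_,
                    mean_theta_hat = NA_real_, n_theta_lt_05 = 0L,
                    n_sites = 0L)
  for (k in seq_len(10L)) {
    j <- which(bin == k)
    out$n_sites[k] <- length(j)
    if (!length(j)) next
    ck <- calls[, j, drop = FALSE]; tk <- truth[, j, drop = FALSE]
    out$share_pct[k] <- if (n_calls_total > 0)
      100 * sum(!is.na(ck)) / n_calls_total else 0
    het <- !is.na(tk) & tk == 1L
    hom <- !is.na(tk) & tk != 1L
    if (any(het & !is.na(ck)))
      out$het_concordance_pct[k] <-
        100 * mean(ck[het & !is.na(ck)] == tk[het & !is.na(ck)])
    if (any(hom & !is.na(ck)))
      out$hom_concordance_pct[k] <-
        100 * mean(ck[hom & !is.na(ck)] == tk[hom & !is.na(ck)])
    out$mean_theta_hat[k] <- mean(theta[j])
    out$n_theta_lt_05[k] <- sum(theta[j] < 0.05)
  }
  out
}

#' GWAS-ready post-imputation site filter
#'
#' Applies the post-imputation QC cascade to the hard-called genotypes:
#' keep sites with call rate > 0.97, Hardy-Weinberg exact p > 5e-5 and
#' MAF > 0.05 (strict drop below each threshold, first failing rule
#' tallied).
#'
#' @param dres a `dosage_result`.
#' @param thresholds a [qc_thresholds()]; default the GWAS-ready preset.
#' @param uncertainty_max hard-call threshold.
#' @return list: `site_ids` (surviving), `report` (per-rule tallies).
#' @export
gwas_ready_filter <- function(dres, thresholds = qc_preset("gwas_ready"),
                              uncertainty_max = 0.1) {
  calls <- hard_call(dres$p0, dres$p1, dres$p2, uncertainty_max)
  ds <- geno_dataset(dres$sites, dres$individuals, calls)
  fs <- filter_sites(ds, thresholds)
  list(site_ids = fs$dataset$sites$site_id, report = fs$report,
       removed = fs$removed)
}
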