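# Study orchestration: the shared imputation pipeline, panel-composition
# ablation, identity-by-state MDS, and the end-to-end driver.

#' Reorient a dataset to an annotation's allele coding
#'
#' Matches sites by `(chrom, pos)`, swaps genotype coding (0 <-> 2) where
#' the dataset's `allele_a`/`allele_b` labels are transposed relative to
#' the annotation, and adopts the annotation's site records (including
#' flanks).  Sites absent from the annotation are dropped.
#'
#' @param ds a `geno_ds`.
#' @param annot a site table (e.g. read with [read_annotation_csv()]).
#' @return the reoriented `geno_ds`.
#' @export
apply_annotation <- function(ds, annot) {
  key_d <- paste(ds$sites$chrom, ds$sites$pos)
  key_a <- paste(annot$chrom, annot$pos)
  i_a <- match(key_d, key_a)
  keep <- which(!is.na(i_a))
  ds <- subset_ds(ds, sites = keep)
  rows <- annot[i_a[keep], , drop = FALSE]
  a_d <- ds$sites$allele_a; b_d <- ds$sites$allele_b
  swap <- !is.na(a_d) & a_d == rows$allele_b &
          (is.na(b_d) | b_d == rows$allele_a)
  ds$genotypes[, swap] <- 2L - ds$genotypes[, swap, drop = FALSE]
  rownames(rows) <- NULL
  ds$sites <- rows
  ds
}

#' Run the imputation pipeline for one hold-out design
#'
#' Panel QC (individual call, site call/MAF), per-chromosome rate filter,
#' study-set strand alignment and QC, reference phasing, windowed
#' imputation, and hold-out evaluation.
#'
#' @param panel a high-density `geno_ds` (held dogs already removed).
#' @param study the low-density `geno_ds` (held dogs included).
#' @param truth held dogs' high-density `geno_ds`.
#' @param map a `genetic_map`.
#' @param params a [model_params()].
#' @param seed integer seed (phasing initialization / conditioning draws).
#' @param qc_panel,qc_study [qc_thresholds()] presets.
#' @return list: `dres`, `eval`, `info_bins`, `gwas`, `panel`, `study`,
#'   `harmonize_report`.
#' @export
run_imputation_study <- function(panel, study, truth, map,
                                 params = model_params(), seed = 1L,
                                 qc_panel = qc_preset("final_panel"),
                                 qc_study = qc_preset("study")) {
  panel <- filter_individuals(panel, qc_panel$min_ind_call)$dataset
  panel <- filter_sites(panel, qc_panel)$dataset
  panel <- chrom_rate_filter(panel, params$min_chrom_rate)$dataset

  al <- align_study_to_panel(study, panel$sites)
  study <- al$dataset
  study <- filter_individuals(study, qc_study$min_ind_call)$dataset
  study <- filter_sites(study, qc_study)$dataset
  study <- chrom_rate_filter(study, params$min_chrom_rate)$dataset

  ref <- phase_reference(panel, map, params, seed = derive_seed(seed, 11L))
  dres <- impute_dataset(study, ref, map, params)
  ev <- evaluate_holdout(dres, truth)
  bins <- stratify_by_info(dres, ev)
  gw <- gwas_ready_filter(dres)
  list(dres = dres, eval = ev, info_bins = bins, gwas = gw,
       panel = panel, study = study, harmonize_report = al$report)
}

#' Panel-composition ablation
#'
#' Re-imputes a fixed hold-out with the breed-specific panel component
#' reduced to each level: dogs are removed at random (nested subsets from
#' one seeded ordering, so lower levels are subsets of higher ones), the
#' panel site list is re-filtered after each removal, and the study set
#' is re-imputed and scored per level.  The multi-breed backbone is never
#' removed.  Panel haplotypes are phased once on the largest panel and
#' restricted per level; the held dogs are never in any panel, so scoring
#' is unaffected.
#'
#' @param scenario a [build_scenario()] result.
#' @param levels breed-specific panel sizes to test (descending or not).
#' @param params a [model_params()].
#' @param n_held held dogs for scoring.
#' @param mode hold-out mode (see [make_holdout()]).
#' @param seed integer seed (hold-out draw, removal order, phasing).
#' @return list: `table` (level, mean_r2, concordance_pct),
#'   `per_individual` (long data.frame), `runs` (eval + info bins per
#'   level), `held_ids`.
#' @export
run_panel_ablation <- function(scenario, levels = c(10L, 20L, 40L, 80L),
                               params = model_params(), n_held = 8L,
                               mode = "regenotyped_overlap", seed = 1L) {
  hd <- make_holdout(scenario, n_held, mode, seed = derive_seed(seed, 1L))
  qc_final <- qc_preset("final_panel")
  panel <- filter_individuals(hd$panel, qc_final$min_ind_call)$dataset
  panel <- chrom_rate_filter(panel, params$min_chrom_rate)$dataset
  focal <- scenario$config$focal_breed
  pool <- panel$individuals$individual_id[panel$individuals$population == focal]
  if (max(levels) > length(pool))
    stop(sprintf("largest level (%d) exceeds available breed-specific dogs (%d)",
                 max(levels), length(pool)))
  ord <- with_seed(derive_seed(seed, 2L), sample(pool))
  backbone <- setdiff(panel$individuals$individual_id, pool)

  # phase once at the largest panel; per-level panels reuse their dogs'
  # haplotypes restricted to the level's re-filtered site list
  top <- c(backbone, ord[seq_len(max(levels))])
  panel_top <- subset_ds(panel, individuals = which(
    panel$individuals$individual_id %in% top))
  panel_top_f <- filter_sites(panel_top, qc_final)$dataset
  ref_top <- phase_reference(panel_top_f, scenario$map, params,
                             seed = derive_seed(seed, 3L))

  al <- align_study_to_panel(hd$study, panel_top_f$sites)
  study <- filter_individuals(al$dataset,
                              qc_preset("study")$min_ind_call)$dataset
  study <- filter_sites(study, qc_preset("study"))$dataset
  study <- chrom_rate_filter(study, params$min_chrom_rate)$dataset

  runs <- list(); rows <- list(); per <- list()
  for (lv in sort(levels, decreasing = TRUE)) {
    keep <- c(backbone, ord[seq_len(lv)])
    panel_lv <- subset_ds(panel_top, individuals = which(
      panel_top$individuals$individual_id %in% keep))
    sites_lv <- filter_sites(panel_lv, qc_final)$dataset$sites$site_id
    sites_lv <- intersect(sites_lv, ref_top$sites$site_id)
    ref_lv <- subset_haps(ref_top, keep)
    cols <- match(sites_lv, ref_lv$sites$site_id)
    ref_lv <- hap_set(ref_lv$sites[cols, , drop = FALSE],
                      ref_lv$individuals,
                      ref_lv$haplotypes[, cols, drop = FALSE])
    s_keep <- which(paste(study$sites$chrom, study$sites$pos) %in%
                    paste(ref_lv$sites$chrom, ref_lv$sites$pos))
    study_lv <- subset_ds(study, sites = s_keep)
    dres <- impute_dataset(study_lv, ref_lv, scenario$map, params)
    ev <- evaluate_holdout(dres, hd$truth)
    bins <- stratify_by_info(dres, ev)
    runs[[as.character(lv)]] <- list(eval = ev, info_bins = bins)
    rows[[as.character(lv)]] <- data.frame(level = lv,
                                           mean_r2 = ev$mean_r2,
                                           concordance_pct = ev$concordance_pct)
    pi <- ev$per_individual
    pi$level <- lv
    per[[as.character(lv)]] <- pi
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$level), ]
  rownames(tab) <- NULL
  list(table = tab, per_individual = do.call(rbind, per), runs = runs,
       held_ids = hd$held_ids)
}

#' Identity-by-state distance matrix
#'
#' `D_ij = 1 - sum(IBS_ij) / (2 n_shared)` with IBS in `{0,1,2}` over
#' sites non-missing in both individuals.
#'
#' @param ds a `geno_ds` with at least 2 individuals.
#' @return symmetric distance matrix with zero diagonal.
#' @export
ibs_distance_matrix <- function(ds) {
  g <- ds$genotypes
  if (nrow(g) < 2L) stop("need at least 2 individuals")
  V <- !is.na(g)
  Gm <- g; Gm[!V] <- 0L
  Gm <- matrix(as.numeric(Gm), nrow(g))
  Vn <- matrix(as.numeric(V), nrow(g))
  n_shared <- Vn %*% t(Vn)
  sq <- (Gm^2) %*% t(Vn)
  cross <- Gm %*% t(Gm)
  A0 <- matrix(as.numeric(g == 0L & V), nrow(g))
  A2 <- matrix(as.numeric(g == 2L & V), nrow(g))
  sum_sqdiff <- sq + t(sq) - 2 * cross
  n_opp <- A0 %*% t(A2) + A2 %*% t(A0)     # |g_i - g_j| == 2
  sum_absdiff <- sum_sqdiff - 2 * n_opp    # (d^2 -> |d|) for d in {0,1,2}
  ibs_sum <- 2 * n_shared - sum_absdiff
  D <- 1 - ibs_sum / (2 * n_shared)
  D[n_shared == 0] <- NA_real_
  diag(D) <- 0
  dimnames(D) <- list(ds$individuals$individual_id,
                      ds$individuals$individual_id)
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-D^2/2` and returns the top-k eigenvector coordinates
#' scaled by the square roots of the eigenvalues, with a deterministic
#' sign convention (first nonzero loading of each axis positive).
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param k number of dimensions (default 2).
#' @return individuals x k coordinate matrix (fewer columns, with a
#'   warning, if fewer positive eigenvalues exist).
#' @export
mds_coordinates <- function(D, k = 2L) {
  if (!isSymmetric(unname(as.matrix(D)), tol = 1e-8))
    stop("distance matrix must be symmetric")
  fit <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  X <- fit$points
  # drop axes whose eigenvalues are zero to numerical precision
  pos_eig <- fit$eig[seq_len(ncol(X))] > max(fit$eig) * 1e-8
  X <- X[, pos_eig, drop = FALSE]
  if (ncol(X) < k)
    warning(sprintf("only %d positive eigenvalue(s); returning %d dimension(s)",
                    ncol(X), ncol(X)))
  for (j in seq_len(ncol(X))) {
    nz <- which(abs(X[, j]) > 1e-12)
    if (length(nz) && X[nz[1], j] < 0) X[, j] <- -X[, j]
  }
  X
}

#' Run the whole study end-to-end on a synthetic scenario
#'
#' simulate -> serialize -> re-read -> harmonize -> QC -> phase -> impute
#' -> evaluate -> (optional) ablation -> MDS, writing every report table
#' under `out_dir` in deterministic plain-text form.
#'
#' @param config a [sim_config()].
#' @param params a [model_params()].
#' @param out_dir output directory.
#' @param seed integer seed for hold-out, phasing and ablation draws.
#' @param n_held held dogs for accuracy scoring.
#' @param mode hold-out mode.
#' @param ablation_levels breed-specific panel sizes for the bundled
#'   ablation, or `NULL` to skip.
#' @return invisibly, a list with the main results and `out_dir`.
#' @export
run_end_to_end <- function(config = sim_config(), params = model_params(),
                           out_dir, seed = 1L, n_held = 8L,
                           mode = "regenotyped_overlap",
                           ablation_levels = NULL) {
  inputs <- file.path(out_dir, "inputs")
  results <- file.path(out_dir, "results")
  dir.create(results, showWarnings = FALSE, recursive = TRUE)

  scenario <- build_scenario(config)
  write_scenario(scenario, inputs)

  # re-read through the standard formats so synthetic and real data enter
  # the pipeline identically
  panel <- read_pedmap(file.path(inputs, "panel.ped"),
                       file.path(inputs, "panel.map"))
  study <- read_pedmap(file.path(inputs, "study.ped"),
                       file.path(inputs, "study.map"))
  hd_annot <- read_annotation_csv(file.path(inputs, "hd_annot.csv"))
  ld_annot <- read_annotation_csv(file.path(inputs, "ld_annot.csv"))
  map <- read_genetic_map(file.path(inputs, "genetic_map.txt"),
                          chrom = config$chrom)
  panel <- apply_annotation(panel, hd_annot)
  study <- apply_annotation(study, ld_annot)
  scen2 <- scenario
  scen2$panel_hd <- panel
  scen2$study_ld <- study

  hd <- make_holdout(scen2, n_held, mode, seed = derive_seed(seed, 21L))
  res <- run_imputation_study(hd$panel, hd$study, hd$truth, map, params,
                              seed = derive_seed(seed, 22L))

  write_gen_sample(res$dres, file.path(results, "imputed"))
  utils::write.table(
    data.frame(site_id = res$dres$sites$site_id, pos = res$dres$sites$pos,
               info = sprintf("%.6f", res$dres$info),
               theta_hat = sprintf("%.6f", res$dres$theta_hat)),
    file.path(results, "info.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_tsv_rounded(res$eval$per_individual,
                    file.path(results, "per_individual.tsv"))
  write_tsv_rounded(res$info_bins, file.path(results, "info_bins.tsv"))
  writeLines(res$gwas$site_ids, file.path(results, "gwas_ready_sites.txt"))
  utils::write.table(data.frame(metric = names(res$harmonize_report),
                                value = as.integer(res$harmonize_report)),
                     file.path(results, "harmonize_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ablation <- NULL
  if (!is.null(ablation_levels)) {
    ablation <- run_panel_ablation(scen2, ablation_levels, params,
                                   n_held = n_held, mode = mode,
                                   seed = derive_seed(seed, 23L))
    write_tsv_rounded(ablation$table, file.path(results, "ablation.tsv"))
  }

  mds <- end_to_end_mds(res, scenario$config)
  write_tsv_rounded(mds, file.path(results, "mds_coordinates.tsv"))

  manifest <- list(seed = seed,
                   config = unclass(config)[order(names(config))],
                   params = unclass(params),
                   n_held = n_held, mode = mode,
                   held_ids = hd$held_ids,
                   mean_r2 = round(res$eval$mean_r2, 6),
                   concordance_pct = round(res$eval$concordance_pct, 4),
                   files = sort(basename(list.files(results))))
  jsonlite::write_json(manifest, file.path(results, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(scenario = scenario, holdout = hd, res = res,
                 ablation = ablation, mds = mds, out_dir = out_dir))
}

# Focal-breed MDS over the sites shared by panel and study, merging the
# high- and low-density genotypes of the focal individuals.
end_to_end_mds <- function(res, config) {
  focal <- config$focal_breed
  p_f <- subset_ds(res$panel,
                   individuals = which(res$panel$individuals$population == focal))
  shared <- paste(p_f$sites$chrom, p_f$sites$pos) %in%
            paste(res$study$sites$chrom, res$study$sites$pos)
  p_f <- subset_ds(p_f, sites = which(shared))
  s_f <- res$study
  s_f$individuals$individual_id <- paste0(s_f$individuals$individual_id, "_ld")
  rownames(s_f$genotypes) <- s_f$individuals$individual_id
  merged <- intersect_and_merge(list(p_f, s_f), source = "mds")$dataset
  D <- ibs_distance_matrix(merged)
  X <- mds_coordinates(D, k = 2L)
  data.frame(individual_id = rownames(X),
             source = ifelse(grepl("_ld$", rownames(X)), "study_ld", "panel_hd"),
             C1 = sprintf("%.6f", X[, 1]),
             C2 = sprintf("%.6f", if (ncol(X) > 1) X[, 2] else 0))
}

# Deterministic TSV writer: numeric columns fixed to 6 decimals.
write_tsv_rounded <- function(df, path) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.6f", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
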