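# Reference-panel construction: QC filtering, allele/strand reconciliation
# via allele codes and flanking sequences, duplicate removal, and
# intersection merging.

#' QC thresholds
#'
#' Drop rules use strict inequality: a record exactly at a threshold is
#' kept.  `hwe_p_min = NULL` or `0` disables the Hardy-Weinberg filter
#' (sequence-derived extractions are not HWE-filtered before merging);
#' `maf_min = 0` disables the MAF filter.
#'
#' @param min_ind_call minimum individual call fraction.
#' @param min_site_call minimum site call fraction.
#' @param hwe_p_min minimum exact Hardy-Weinberg p-value, or NULL.
#' @param maf_min minimum minor allele frequency.
#' @param min_gq minimum Phred genotype quality for sequence-derived calls.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_ind_call = 0.90, min_site_call = 0.97,
                          hwe_p_min = 5e-5, maf_min = 0.01, min_gq = 20) {
  fr <- c(min_ind_call, min_site_call, maf_min)
  if (any(fr < 0 | fr > 1)) stop("call/MAF thresholds must lie in [0,1]")
  structure(list(min_ind_call = min_ind_call, min_site_call = min_site_call,
                 hwe_p_min = hwe_p_min, maf_min = maf_min, min_gq = min_gq),
            class = "qc_thresholds")
}

#' Preset threshold sets
#'
#' `panel_input`: array/sequence inputs before merging (individual call
#' 0.90, site call 0.97; HWE only for array data, no MAF filter).
#' `study`: study sets (0.95 / 0.97 / HWE 5e-5 / MAF 0.01).
#' `final_panel`: the pooled panel (0.95 / 0.97 / MAF 0.01, no HWE).
#' `gwas_ready`: post-imputation GWAS filter (call 0.97, HWE 5e-5, MAF 0.05).
#'
#' @param which preset name.
#' @param hwe apply the HWE filter (used by `panel_input` for array data).
#' @return a [qc_thresholds()].
#' @export
qc_preset <- function(which = c("panel_input", "study", "final_panel",
                                "gwas_ready"), hwe = TRUE) {
  switch(match.arg(which),
    panel_input = qc_thresholds(0.90, 0.97,
                                if (hwe) 5e-5 else NULL, maf_min = 0),
    study       = qc_thresholds(0.95, 0.97, 5e-5, 0.01),
    final_panel = qc_thresholds(0.95, 0.97, NULL, 0.01),
    gwas_ready  = qc_thresholds(0, 0.97, 5e-5, 0.05))
}

#' Filter individuals by call rate
#'
#' @param ds a `geno_ds`.
#' @param min_ind_call minimum call fraction (strict drop below).
#' @return list: `dataset`, `removed_ids`.
#' @export
filter_individuals <- function(ds, min_ind_call = 0.90) {
  rates <- individual_call_rates(ds)
  drop <- rates < min_ind_call
  if (all(drop)) warning("all individuals removed by call-rate filter")
  list(dataset = subset_ds(ds, individuals = which(!drop)),
       removed_ids = ds$individuals$individual_id[drop])
}

#' Filter sites by call rate, Hardy-Weinberg and MAF
#'
#' Rules apply in order - call rate, then HWE, then MAF - and each removed
#' site is tallied once under the first rule it fails.
#'
#' @param ds a `geno_ds`.
#' @param thresholds a [qc_thresholds()].
#' @return list: `dataset`, `report` (data.frame rule/n_removed),
#'   `removed` (site_id -> rule).
#' @export
filter_sites <- function(ds, thresholds) {
  g <- ds$genotypes
  call_ok <- site_call_rates(ds) >= thresholds$min_site_call
  hwe_ok <- rep(TRUE, ncol(g))
  do_hwe <- !is.null(thresholds$hwe_p_min) && thresholds$hwe_p_min > 0
  if (do_hwe && ncol(g)) {
    cand <- which(call_ok)
    if (length(cand)) {
      n_aa <- colSums(g[, cand, drop = FALSE] == 0L, na.rm = TRUE)
      n_ab <- colSums(g[, cand, drop = FALSE] == 1L, na.rm = TRUE)
      n_bb <- colSums(g[, cand, drop = FALSE] == 2L, na.rm = TRUE)
      nonempty <- (n_aa + n_ab + n_bb) >= 1L
      p <- rep(1, length(cand))
      p[nonempty] <- hwe_exact_test(n_aa[nonempty], n_ab[nonempty],
                                    n_bb[nonempty])
      hwe_ok[cand] <- p >= thresholds$hwe_p_min
    }
  }
  maf_ok <- rep(TRUE, ncol(g))
  if (thresholds$maf_min > 0 && ncol(g)) {
    maf <- site_maf(ds)
    maf_ok <- !is.na(maf) & maf >= thresholds$maf_min
  }
  rule <- rep(NA_character_, ncol(g))
  rule[call_ok & hwe_ok & !maf_ok] <- "maf"
  rule[call_ok & !hwe_ok] <- "hwe"
  rule[!call_ok] <- "call_rate"
  keep <- is.na(rule)
  removed <- stats::setNames(rule[!keep], ds$sites$site_id[!keep])
  report <- data.frame(rule = c("call_rate", "hwe", "maf"),
                       n_removed = c(sum(rule == "call_rate", na.rm = TRUE),
                                     sum(rule == "hwe", na.rm = TRUE),
                                     sum(rule == "maf", na.rm = TRUE)))
  list(dataset = subset_ds(ds, sites = which(keep)),
       report = report, removed = removed)
}

#' Classify an allele pair across two annotations
#'
#' @param a,b single-row site records at the same `(chrom, pos)`.
#' @return list `decision` in `same`, `flip`, `ambiguous_palindromic`,
#'   `mismatch`; `evidence` in `alleles`, `none`.
#' @export
classify_allele_pair <- function(a, b) {
  if (a$chrom != b$chrom || a$pos != b$pos)
    stop("records are at different positions")
  set_a <- c(a$allele_a, a$allele_b)
  set_b <- c(b$allele_a, b$allele_b)
  if (anyNA(set_a) || anyNA(set_b))
    return(list(decision = "mismatch", evidence = "none"))
  pal_a <- setequal(set_a, complement_base(set_a))
  if (pal_a && setequal(set_a, set_b))
    return(list(decision = "ambiguous_palindromic", evidence = "none"))
  if (setequal(set_a, set_b))
    return(list(decision = "same", evidence = "alleles"))
  if (setequal(complement_base(set_a), set_b))
    return(list(decision = "flip", evidence = "alleles"))
  list(decision = "mismatch", evidence = "none")
}

#' Resolve strand by flanking sequence
#'
#' Compares `b`'s flanks, truncated to `k` bases adjacent to the site,
#' against `a`'s: equal means same strand; equal to the swapped reverse
#' complements means flipped.
#'
#' @param a,b single-row site records carrying flanks of length >= k.
#' @param k bases of context to compare (default 10).
#' @return list `decision`, `evidence` (`flanks` or `none`).
#' @export
resolve_by_flanks <- function(a, b, k = 10L) {
  fa_u <- a$flank_up; fa_d <- a$flank_down
  fb_u <- b$flank_up; fb_d <- b$flank_down
  if (anyNA(c(fa_u, fa_d, fb_u, fb_d)))
    stop("flanks missing")
  if (min(nchar(c(fa_u, fa_d, fb_u, fb_d))) < k)
    stop("flanks shorter than k")
  # keep the k bases adjacent to the site: tail of upstream, head of down
  tail_k <- function(x) substring(x, nchar(x) - k + 1L, nchar(x))
  head_k <- function(x) substring(x, 1L, k)
  same <- identical(tail_k(fb_u), tail_k(fa_u)) &&
          identical(head_k(fb_d), head_k(fa_d))
  flip <- identical(tail_k(fb_u), tail_k(revcomp(fa_d))) &&
          identical(head_k(fb_d), head_k(revcomp(fa_u)))
  if (same) list(decision = "same", evidence = "flanks")
  else if (flip) list(decision = "flip", evidence = "flanks")
  else list(decision = "mismatch", evidence = "none")
}

#' Decide strand orientation for every shared site
#'
#' Allele-code comparison first; palindromic pairs fall back to flanking
#' sequence when both annotations carry flanks, and stay ambiguous
#' otherwise.
#'
#' @param ref_sites reference-orientation site table.
#' @param qry_sites query site table (e.g. a study-set annotation).
#' @param k flank bases to compare.
#' @return data.frame: `site_id`, `decision`, `evidence` for sites shared
#'   by `(chrom, pos)`.
#' @export
decide_strands <- function(ref_sites, qry_sites, k = 10L) {
  key_r <- paste(ref_sites$chrom, ref_sites$pos)
  key_q <- paste(qry_sites$chrom, qry_sites$pos)
  shared <- intersect(key_r, key_q)
  ir <- match(shared, key_r); iq <- match(shared, key_q)
  out <- data.frame(site_id = qry_sites$site_id[iq],
                    decision = character(length(shared)),
                    evidence = character(length(shared)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(shared)) {
    a <- ref_sites[ir[i], ]; b <- qry_sites[iq[i], ]
    d <- classify_allele_pair(a, b)
    has_flanks <- !anyNA(c(a$flank_up, a$flank_down, b$flank_up, b$flank_down))
    if (has_flanks && d$decision %in% c("ambiguous_palindromic", "same", "flip")) {
      # flanks are decisive when available; for non-palindromic sites they
      # must agree with the allele-code call, otherwise flag a mismatch
      df <- resolve_by_flanks(a, b, k)
      if (d$decision == "ambiguous_palindromic") d <- df
      else if (df$decision != d$decision) d <- list(decision = "mismatch",
                                                    evidence = "none")
    }
    out$decision[i] <- d$decision
    out$evidence[i] <- d$evidence
  }
  out
}

#' Apply strand flips to a dataset
#'
#' Flipped sites have their allele letters complemented (and flanks
#' reverse-complemented and swapped); genotype codes are untouched since
#' coding follows the allele letters.  Sites decided `mismatch` or left
#' `ambiguous_palindromic` are excluded.
#'
#' @param ds a `geno_ds`.
#' @param decisions data.frame from [decide_strands()].
#' @return list: `dataset`, `report` (counts of flips applied, palindromic
#'   resolved by flank, excluded mismatches / unresolved).
#' @export
apply_strand_flips <- function(ds, decisions) {
  idx <- match(decisions$site_id, ds$sites$site_id)
  if (anyNA(idx)) stop("decisions reference unknown sites")
  flip_i <- idx[decisions$decision == "flip"]
  drop_i <- idx[decisions$decision %in% c("mismatch", "ambiguous_palindromic")]
  s <- ds$sites
  if (length(flip_i)) {
    fu <- s$flank_up[flip_i]; fd <- s$flank_down[flip_i]
    s$allele_a[flip_i] <- complement_base(s$allele_a[flip_i])
    s$allele_b[flip_i] <- complement_base(s$allele_b[flip_i])
    ok <- !is.na(fu) & !is.na(fd)
    s$flank_up[flip_i[ok]] <- revcomp(fd[ok])
    s$flank_down[flip_i[ok]] <- revcomp(fu[ok])
  }
  ds$sites <- s
  keep <- setdiff(seq_len(nrow(s)), drop_i)
  report <- c(flips_applied = length(flip_i),
              palindromic_resolved_by_flank =
                sum(decisions$decision %in% c("same", "flip") &
                    decisions$evidence == "flanks"),
              excluded_mismatch = sum(decisions$decision == "mismatch"),
              excluded_ambiguous =
                sum(decisions$decision == "ambiguous_palindromic"))
  list(dataset = subset_ds(ds, sites = keep), report = report)
}

#' Remove duplicate sites at one genomic position
#'
#' Among records sharing `(chrom, pos)` the record with the highest call
#' rate is kept; ties break to the lexicographically smallest site_id.
#'
#' @param ds a `geno_ds`.
#' @return list: `dataset`, `n_removed`.
#' @export
dedup_sites <- function(ds) {
  key <- paste(ds$sites$chrom, ds$sites$pos)
  if (!anyDuplicated(key))
    return(list(dataset = ds, n_removed = 0L))
  rates <- site_call_rates(ds)
  ord <- order(key, -rates, ds$sites$site_id)
  keep_sorted <- ord[!duplicated(key[ord])]
  keep <- sort(keep_sorted)
  list(dataset = subset_ds(ds, sites = keep),
       n_removed = ncol(ds$genotypes) - length(keep))
}

#' Intersect and merge strand-harmonized datasets
#'
#' Site list is the `(chrom, pos)` intersection with identical allele
#' sets; individuals are concatenated.  Where two datasets label the same
#' allele pair with transposed `allele_a`/`allele_b`, the second coding is
#' swapped (genotypes 0 <-> 2) so "allele 1" identity holds everywhere.
#'
#' @param datasets list of `geno_ds` with disjoint individual ids.
#' @param source tag for the merged site table.
#' @return list: `dataset`, `report` (`excluded_conflict` count and ids).
#' @export
intersect_and_merge <- function(datasets, source = "merged") {
  stopifnot(length(datasets) >= 1L)
  ids <- unlist(lapply(datasets, function(d) d$individuals$individual_id))
  if (anyDuplicated(ids)) stop("shared individual ids across datasets")
  keys <- lapply(datasets, function(d) paste(d$sites$chrom, d$sites$pos))
  shared <- Reduce(intersect, keys)
  ref <- datasets[[1]]
  i_ref <- match(shared, keys[[1]])
  ord <- order(ref$sites$chrom[i_ref], ref$sites$pos[i_ref])
  shared <- shared[ord]; i_ref <- i_ref[ord]

  conflict <- rep(FALSE, length(shared))
  parts <- vector("list", length(datasets))
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    i_d <- match(shared, keys[[d]])
    g <- ds$genotypes[, i_d, drop = FALSE]
    a_ref <- ref$sites$allele_a[i_ref]; b_ref <- ref$sites$allele_b[i_ref]
    a_d <- ds$sites$allele_a[i_d]; b_d <- ds$sites$allele_b[i_d]
    same_order <- !is.na(a_d) & !is.na(b_d) & a_d == a_ref & b_d == b_ref
    transposed <- !is.na(a_d) & !is.na(b_d) & a_d == b_ref & b_d == a_ref
    mono_ok <- is.na(b_d) & !is.na(a_d) & (a_d == a_ref | a_d == b_ref)
    # monomorphic record: observed letter fixes the coding
    mono_swap <- mono_ok & a_d == b_ref
    g[, transposed | mono_swap] <- 2L - g[, transposed | mono_swap, drop = FALSE]
    conflict <- conflict | !(same_order | transposed | mono_ok)
    parts[[d]] <- g
  }
  keep <- !conflict
  sites <- ref$sites[i_ref[keep], , drop = FALSE]
  sites$source <- source
  rownames(sites) <- NULL
  ind <- do.call(rbind, lapply(datasets, `[[`, "individuals"))
  g_all <- do.call(rbind, lapply(parts, function(g) g[, keep, drop = FALSE]))
  list(dataset = geno_dataset(sites, ind, g_all),
       report = list(excluded_conflict = sum(conflict),
                     conflict_ids = ref$sites$site_id[i_ref[!keep]]))
}

#' Align a study set to a reference panel orientation
#'
#' Strand decisions against the panel annotation (allele codes, then
#' flanks for palindromic sites), flips applied, and sites restricted to
#' those present in the panel.
#'
#' @param study a `geno_ds` carrying its own annotation dialect.
#' @param panel_sites panel-orientation site table with flanks.
#' @param k flank bases to compare.
#' @return list: `dataset`, `decisions`, `report`.
#' @export
align_study_to_panel <- function(study, panel_sites, k = 10L) {
  dec <- decide_strands(panel_sites, study$sites, k = k)
  res <- apply_strand_flips(study, dec)
  keep <- paste(res$dataset$sites$chrom, res$dataset$sites$pos) %in%
          paste(panel_sites$chrom, panel_sites$pos)
  list(dataset = subset_ds(res$dataset, sites = which(keep)),
       decisions = dec, report = res$report)
}
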