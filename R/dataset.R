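# Core containers: genotype datasets, haplotype sets, site tables.
#
# A site table is a data.frame with columns chrom, pos, site_id, allele_a,
# allele_b, flank_up, flank_down, source.  Genotypes count copies of
# allele_b ("allele 1"), the dosage-counted allele throughout the package.

SITE_COLS <- c("chrom", "pos", "site_id", "allele_a", "allele_b",
               "flank_up", "flank_down", "source")

#' Build a site table
#'
#' @param chrom chromosome labels.
#' @param pos 1-based base-pair positions.
#' @param site_id site identifiers (default `chrom_pos`).
#' @param allele_a,allele_b allele letters; `allele_b` is the counted allele.
#' @param flank_up,flank_down optional flanking sequences (uppercase DNA).
#' @param source free-text dataset tag.
#' @return data.frame with the canonical site columns, ordered as given.
#' @export
site_table <- function(chrom, pos, site_id = NULL,
                       allele_a = NA_character_, allele_b = NA_character_,
                       flank_up = NA_character_, flank_down = NA_character_,
                       source = NA_character_) {
  n <- length(pos)
  if (is.null(site_id))
    site_id <- if (n == 0L) character(0) else paste0(chrom, "_", pos)
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   pos = as.integer(pos),
                   site_id = as.character(site_id),
                   allele_a = rep_len(as.character(allele_a), n),
                   allele_b = rep_len(as.character(allele_b), n),
                   flank_up = rep_len(as.character(flank_up), n),
                   flank_down = rep_len(as.character(flank_down), n),
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  stopifnot(nrow(df) == n, all(df$pos >= 1))
  ok <- is.na(df$allele_a) | is.na(df$allele_b) | df$allele_a != df$allele_b
  if (!all(ok)) stop("allele_a must differ from allele_b")
  df
}

#' Construct a genotype dataset
#'
#' @param sites site table (see [site_table()]), strictly increasing in
#'   `(chrom, pos)` within chromosome.
#' @param individuals data.frame with columns `individual_id`, `population`.
#' @param genotypes integer matrix, individuals x sites, entries in
#'   `{0,1,2,NA}` counting copies of `allele_b`.
#' @param qualities optional matching matrix of per-genotype Phred scores.
#' @return an object of class `geno_ds`.
#' @export
geno_dataset <- function(sites, individuals, genotypes, qualities = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(individuals))
    stop("genotype rows must match individuals")
  if (ncol(genotypes) != nrow(sites))
    stop("genotype columns must match sites")
  if (anyDuplicated(individuals$individual_id))
    stop("duplicate individual ids")
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L))
    stop("genotype entries must be 0, 1, 2 or NA")
  o <- order(sites$chrom, sites$pos)
  if (!identical(o, seq_len(nrow(sites)))) {
    sites <- sites[o, , drop = FALSE]
    genotypes <- genotypes[, o, drop = FALSE]
    if (!is.null(qualities)) qualities <- qualities[, o, drop = FALSE]
  }
  rownames(genotypes) <- individuals$individual_id
  colnames(genotypes) <- sites$site_id
  structure(list(sites = sites,
                 individuals = as.data.frame(individuals),
                 genotypes = genotypes,
                 qualities = qualities),
            class = "geno_ds")
}

#' @export
print.geno_ds <- function(x, ...) {
  cat(sprintf("<geno_ds> %d individuals x %d sites, %.1f%% missing\n",
              nrow(x$genotypes), ncol(x$genotypes),
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' @export
dim.geno_ds <- function(x) dim(x$genotypes)

#' Subset a genotype dataset
#'
#' @param ds a `geno_ds`.
#' @param individuals row selector (ids, logical or integer indices).
#' @param sites column selector (site_ids, logical or integer indices).
#' @return the subset `geno_ds`.
#' @export
subset_ds <- function(ds, individuals = NULL, sites = NULL) {
  ri <- seq_len(nrow(ds$genotypes))
  ci <- seq_len(ncol(ds$genotypes))
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals))
      match(individuals, ds$individuals$individual_id) else which_idx(individuals, length(ri))
    if (anyNA(ri)) stop("unknown individual id")
  }
  if (!is.null(sites)) {
    ci <- if (is.character(sites)) match(sites, ds$sites$site_id)
          else which_idx(sites, length(ci))
    if (anyNA(ci)) stop("unknown site id")
  }
  geno_dataset(ds$sites[ci, , drop = FALSE],
               ds$individuals[ri, , drop = FALSE],
               ds$genotypes[ri, ci, drop = FALSE],
               if (!is.null(ds$qualities)) ds$qualities[ri, ci, drop = FALSE])
}

which_idx <- function(sel, n) {
  if (is.logical(sel)) { stopifnot(length(sel) == n); which(sel) }
  else as.integer(sel)
}

#' Construct a haplotype set
#'
#' Phased binary haplotypes, two per individual; row `2i-1` and `2i` belong
#' to individual `i`.
#'
#' @param sites site table.
#' @param individuals data.frame with `individual_id`, `population`.
#' @param haplotypes integer matrix (2 x n_individuals) x sites in `{0,1}`,
#'   indicating copies of `allele_b`.
#' @return an object of class `hap_set`.
#' @export
hap_set <- function(sites, individuals, haplotypes) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) != 2L * nrow(individuals))
    stop("need two haplotypes per individual")
  if (ncol(haplotypes) != nrow(sites))
    stop("haplotype columns must match sites")
  vals <- haplotypes[!is.na(haplotypes)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 1L))
    stop("haplotypes must be binary")
  structure(list(sites = sites, individuals = as.data.frame(individuals),
                 haplotypes = haplotypes),
            class = "hap_set")
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf("<hap_set> %d individuals (%d haplotypes) x %d sites\n",
              nrow(x$individuals), nrow(x$haplotypes), nrow(x$sites)))
  invisible(x)
}

#' Collapse haplotypes to genotypes (error-free)
#'
#' @param haps a `hap_set`.
#' @return a `geno_ds` whose genotypes are the haplotype pair sums.
#' @export
haps_to_genotypes <- function(haps) {
  n <- nrow(haps$individuals)
  g <- haps$haplotypes[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       haps$haplotypes[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  geno_dataset(haps$sites, haps$individuals, g)
}

#' Subset a haplotype set by individuals
#'
#' @param haps a `hap_set`.
#' @param ids individual ids to keep.
#' @return the subset `hap_set`.
#' @export
subset_haps <- function(haps, ids) {
  ri <- match(ids, haps$individuals$individual_id)
  if (anyNA(ri)) stop("unknown individual id")
  hrows <- as.vector(rbind(2L * ri - 1L, 2L * ri))
  hap_set(haps$sites, haps$individuals[ri, , drop = FALSE],
          haps$haplotypes[hrows, , drop = FALSE])
}

# Per-individual call rate; degenerate zero-site dataset counts as fully
# called (rate 1) so it passes call-rate filters.
individual_call_rates <- function(ds) {
  if (ncol(ds$genotypes) == 0L)
    return(stats::setNames(rep(1, nrow(ds$genotypes)),
                           ds$individuals$individual_id))
  rowMeans(!is.na(ds$genotypes))
}

site_call_rates <- function(ds) {
  if (nrow(ds$genotypes) == 0L) return(rep(1, ncol(ds$genotypes)))
  colMeans(!is.na(ds$genotypes))
}

# Allele-b frequency among non-missing calls; NA where nothing is called.
site_freq_b <- function(ds) {
  n_called <- colSums(!is.na(ds$genotypes))
  colSums(ds$genotypes, na.rm = TRUE) / (2 * n_called)
}

site_maf <- function(ds) {
  f <- site_freq_b(ds)
  pmin(f, 1 - f)
}

# Mean absolute genotype difference between rows of A and rows of B over
# sites non-missing in both (genotypes in {0,1,2,NA}).  Used to pick
# copying-model conditioning states by similarity.
cross_mean_absdiff <- function(A, B) {
  VA <- !is.na(A); VB <- !is.na(B)
  A0 <- A; A0[!VA] <- 0L; B0 <- B; B0[!VB] <- 0L
  A0 <- matrix(as.numeric(A0), nrow(A)); B0 <- matrix(as.numeric(B0), nrow(B))
  VAn <- matrix(as.numeric(VA), nrow(A)); VBn <- matrix(as.numeric(VB), nrow(B))
  n_sh <- VAn %*% t(VBn)
  sq <- (A0^2) %*% t(VBn) + VAn %*% t(B0^2) - 2 * A0 %*% t(B0)
  n_opp <- matrix(as.numeric(A == 0L & VA), nrow(A)) %*%
             t(matrix(as.numeric(B == 2L & VB), nrow(B))) +
           matrix(as.numeric(A == 2L & VA), nrow(A)) %*%
             t(matrix(as.numeric(B == 0L & VB), nrow(B)))
  (sq - 2 * n_opp) / pmax(n_sh, 1)   # |d| = d^2 - 2*[|d| == 2]
}
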