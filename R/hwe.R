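# Exact test of Hardy-Weinberg equilibrium.

#' Exact Hardy-Weinberg test
#'
#' Two-sided exact test of the Levene-Haldane conditional distribution of
#' the heterozygote count given the allele counts: the p-value is the sum
#' of the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom `allele_a`, het, hom
#'   `allele_b`); vectors are recycled to a common length.
#' @return p-values in `(0, 1]`; monomorphic samples give 1.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- max(length(n_aa), length(n_ab), length(n_bb))
  n_aa <- rep_len(as.integer(n_aa), n)
  n_ab <- rep_len(as.integer(n_ab), n)
  n_bb <- rep_len(as.integer(n_bb), n)
  if (any(n_aa < 0 | n_ab < 0 | n_bb < 0)) stop("negative genotype counts")
  if (any(n_aa + n_ab + n_bb < 1)) stop("empty sample")
  vapply(seq_len(n), function(i) {
    hwe_exact_one(n_aa[i], n_ab[i], n_bb[i])
  }, numeric(1))
}

# Conditional log-probability (up to an additive constant) of heterozygote
# count h given allele counts; normalized via log-sum-exp over the support.
hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  n_min <- min(n_a, n_b)
  if (n_min == 0L) return(1)            # monomorphic: single support point
  h <- seq.int(n_min %% 2L, n_min, by = 2L)
  logw <- h * log(2) -
    lgamma((n_a - h) / 2 + 1) - lgamma(h + 1) - lgamma((n_b - h) / 2 + 1)
  logw <- logw - max(logw)
  w <- exp(logw)
  p_all <- w / sum(w)
  p_obs <- p_all[match(n_ab, h)]
  # relative guard so mathematically tied masses compare as tied in floats
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-12)]))
}
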