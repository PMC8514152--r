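# The computational core: haplotype phasing and genotype imputation under
# a Li-Stephens haplotype-copying HMM with genetic-map-scaled switching.
#
# Parameterization: for an interval of genetic length d Morgans and K
# reference haplotypes, rho = 4 * Ne * d and the per-haplotype template
# switch probability is s = 1 - exp(-rho / K); conditional on a switch the
# new template is uniform over the K haplotypes.  Miscopying uses
# lambda = theta / (2 (theta + K)) with Watterson-style
# theta = 1 / sum_{i=1}^{K-1} 1/i.

#' Copying-model parameters
#'
#' @param ne effective population size scaling recombination (default 200).
#' @param window_bp processing window length (default 2 Mb).
#' @param overlap_bp stitch buffer between adjacent windows (default 250 kb);
#'   `window_bp` must exceed `2 * overlap_bp`.
#' @param theta miscopy parameter; `NULL` for the Watterson default, which
#'   depends on the reference size.
#' @param min_chrom_rate per-chromosome individual call threshold.
#' @param phase_states number of reference haplotypes conditioned on when
#'   phasing a reference panel internally (random seeded subset).
#' @param phase_rounds_min,phase_rounds_max iterative-phasing round bounds.
#' @return a `model_params` list.
#' @export
model_params <- function(ne = 200, window_bp = 2e6, overlap_bp = 250e3,
                         theta = NULL, min_chrom_rate = 0.90,
                         phase_states = 40L, phase_rounds_min = 2L,
                         phase_rounds_max = 10L) {
  if (ne <= 0) stop("ne must be positive")
  if (window_bp <= 2 * overlap_bp) stop("window_bp must exceed 2*overlap_bp")
  if (!is.null(theta) && (theta <= 0 || theta >= 1))
    stop("theta must lie in (0,1)")
  structure(list(ne = ne, window_bp = window_bp, overlap_bp = overlap_bp,
                 theta = theta, min_chrom_rate = min_chrom_rate,
                 phase_states = as.integer(phase_states),
                 phase_rounds_min = as.integer(phase_rounds_min),
                 phase_rounds_max = as.integer(phase_rounds_max)),
            class = "model_params")
}

#' Watterson-style miscopy parameters
#'
#' @param K number of reference haplotypes.
#' @param theta optional override of the mutation/miscopy parameter.
#' @return the per-site miscopy probability lambda.
#' @export
miscopy_lambda <- function(K, theta = NULL) {
  if (K < 1) stop("empty reference")
  if (is.null(theta))
    theta <- if (K <= 1L) 1 else 1 / sum(1 / seq_len(K - 1L))
  theta / (2 * (theta + K))
}

#' Per-interval template switch probabilities
#'
#' @param cm genetic positions (cM) of the sites, in order.
#' @param ne effective population size.
#' @param K number of reference haplotypes.
#' @return vector of `length(cm) - 1` switch probabilities
#'   `1 - exp(-4 ne d / K)` with `d` in Morgans.
#' @export
transition_weights <- function(cm, ne, K) {
  d <- diff(cm) / 100
  if (any(d < 0)) stop("map error: negative genetic distance")
  1 - exp(-4 * ne * d / K)
}

switch_prob <- function(d_morgan, ne, K) 1 - exp(-4 * ne * d_morgan / K)

#' Per-chromosome individual call filter
#'
#' @param ds a single-chromosome `geno_ds`.
#' @param min_chrom_rate minimum call fraction on this chromosome.
#' @return list: `dataset`, `removed_ids`.
#' @export
chrom_rate_filter <- function(ds, min_chrom_rate = 0.90) {
  if (length(unique(ds$sites$chrom)) > 1L)
    stop("chrom_rate_filter expects a single-chromosome dataset")
  filter_individuals(ds, min_chrom_rate)
}

#' Haploid copying-model imputation (forward-backward)
#'
#' Runs the forward-backward recursion over K copying states at the typed
#' sites and carries the state posterior across each untyped interval,
#' yielding a per-site posterior probability of allele 1.
#'
#' @param obs observed alleles (0/1/NA) at the typed sites.
#' @param typed_idx indices of the typed sites within the reference site
#'   list (strictly increasing).
#' @param ref_haps K x M reference haplotype matrix (0/1).
#' @param cm genetic positions (cM) of all M reference sites.
#' @param ne effective population size.
#' @param theta optional miscopy parameter override.
#' @return list: `q` (length-M allele-1 posterior), `loglik` (log
#'   likelihood of the observed alleles).
#' @export
impute_haploid <- function(obs, typed_idx, ref_haps, cm, ne = 200,
                           theta = NULL) {
  K <- nrow(ref_haps); M <- ncol(ref_haps)
  if (is.null(K) || K < 1L) stop("empty reference panel")
  lambda <- miscopy_lambda(K, theta)
  Tn <- length(typed_idx)
  if (Tn == 0L) {
    return(list(q = colMeans(ref_haps), loglik = 0))
  }
  stopifnot(length(obs) == Tn, !is.unsorted(typed_idx, strictly = TRUE))
  cmt <- cm[typed_idx]
  s <- transition_weights(cmt, ne, K)
  A <- t(ref_haps[, typed_idx, drop = FALSE])   # T x K template alleles
  E <- matrix(lambda, Tn, K)
  E[A == obs] <- 1 - lambda                      # column-wise recycling
  E[is.na(obs), ] <- 1

  f <- matrix(0, Tn, K)
  loglik <- 0
  v <- E[1, ] / K
  cv <- sum(v); f[1, ] <- v / cv; loglik <- log(cv)
  if (Tn > 1L) for (t in 2:Tn) {
    pred <- (1 - s[t - 1]) * f[t - 1, ] + s[t - 1] / K
    v <- pred * E[t, ]
    cv <- sum(v); f[t, ] <- v / cv; loglik <- loglik + log(cv)
  }
  b <- matrix(0, Tn, K)
  b[Tn, ] <- 1 / K
  if (Tn > 1L) for (t in (Tn - 1L):1L) {
    eb <- E[t + 1, ] * b[t + 1, ]
    v <- (1 - s[t]) * eb + s[t] * mean(eb)
    b[t, ] <- v / sum(v)
  }

  P <- matrix(0, M, K)
  post_t <- f * b
  P[typed_idx, ] <- post_t / rowSums(post_t)
  if (M > Tn) {
    bounds <- c(0L, typed_idx, M + 1L)
    cmb <- c(cmt[1], cmt, cmt[Tn])
    for (seg in seq_len(Tn + 1L)) {
      lo <- bounds[seg] + 1L; hi <- bounds[seg + 1L] - 1L
      if (lo > hi) next
      u <- lo:hi
      if (seg == 1L) {                      # before first typed site
        eb <- E[1, ] * b[1, ]; cb <- eb / sum(eb)
        sr <- switch_prob((cmt[1] - cm[u]) / 100, ne, K)
        G <- matrix(1 / K, length(u), K)
        H <- outer(1 - sr, cb) + sr / K
      } else if (seg == Tn + 1L) {          # after last typed site
        sl <- switch_prob((cm[u] - cmt[Tn]) / 100, ne, K)
        G <- outer(1 - sl, f[Tn, ]) + sl / K
        H <- matrix(1 / K, length(u), K)
      } else {
        tl <- seg - 1L
        sl <- switch_prob((cm[u] - cmt[tl]) / 100, ne, K)
        sr <- switch_prob((cmt[tl + 1L] - cm[u]) / 100, ne, K)
        eb <- E[tl + 1L, ] * b[tl + 1L, ]; cb <- eb / sum(eb)
        G <- outer(1 - sl, f[tl, ]) + sl / K
        H <- outer(1 - sr, cb) + sr / K
      }
      W <- G * H
      P[u, ] <- W / rowSums(W)
    }
  }
  q <- rowSums(P * t(ref_haps))
  list(q = q, loglik = loglik)
}

#' Diploid copying-model phasing (Viterbi)
#'
#' Most probable path through the K x K diploid copying HMM; the returned
#' haplotype pair reproduces the genotypes exactly at non-missing sites.
#' At heterozygous sites where the two chosen templates agree (phase not
#' informed by the path), allele 1 goes to the first haplotype.
#'
#' @param g genotypes at the typed sites (0/1/2/NA).
#' @param ref_haps K x T reference haplotypes at the typed sites.
#' @param cm genetic positions (cM) of the typed sites.
#' @param ne effective population size.
#' @param theta optional miscopy override.
#' @return list: `h1`, `h2` (0/1 vectors), `path` (T x 2 template
#'   indices), `score` (log probability of the path).
#' @export
phase_diploid <- function(g, ref_haps, cm, ne = 200, theta = NULL) {
  K <- nrow(ref_haps); Tn <- length(g)
  if (is.null(K) || K < 1L) stop("empty reference panel")
  stopifnot(ncol(ref_haps) == Tn, length(cm) == Tn)
  lambda <- miscopy_lambda(K, theta)
  s <- transition_weights(cm, ne, K)
  gi <- as.integer(g); gi[is.na(gi)] <- -1L
  vit <- diploid_viterbi_cpp(gi, ref_haps, s, lambda)
  a1 <- ref_haps[cbind(vit$k1, seq_len(Tn))]
  a2 <- ref_haps[cbind(vit$k2, seq_len(Tn))]
  h1 <- a1; h2 <- a2
  hom0 <- !is.na(g) & g == 0L; hom2 <- !is.na(g) & g == 2L
  het <- !is.na(g) & g == 1L
  h1[hom0] <- 0L; h2[hom0] <- 0L
  h1[hom2] <- 1L; h2[hom2] <- 1L
  tie <- het & a1 == a2                # templates agree: phase uninformed
  h1[het] <- a1[het]; h2[het] <- 1L - a1[het]
  h1[tie] <- 1L; h2[tie] <- 0L
  list(h1 = as.integer(h1), h2 = as.integer(h2),
       path = cbind(k1 = vit$k1, k2 = vit$k2), score = vit$score)
}

#' Iteratively phase a reference panel
#'
#' Initializes every individual with a random genotype-consistent phase,
#' then repeatedly re-phases each individual against a seeded random
#' subset of the current haplotypes of the others, until no heterozygous
#' assignment changes (minimum 2 rounds) or the round cap is reached.
#'
#' @param ds a single-chromosome `geno_ds`.
#' @param map a `genetic_map`.
#' @param params a [model_params()].
#' @param seed integer seed.
#' @return a [hap_set()]; pair sums equal the genotypes at non-missing sites.
#' @export
phase_reference <- function(ds, map, params = model_params(), seed = 1L) {
  g <- ds$genotypes
  n <- nrow(g); m <- ncol(g)
  cm <- interpolate_cm(map, ds$sites$pos)
  with_seed(seed, {
    freq <- site_freq_b(ds); freq[is.na(freq)] <- 0.5
    h <- matrix(0L, 2L * n, m)
    for (i in seq_len(n)) {
      gi <- g[i, ]
      a <- ifelse(is.na(gi), stats::rbinom(m, 1L, freq), as.integer(gi >= 1L))
      b <- ifelse(is.na(g[i, ]), stats::rbinom(m, 1L, freq),
                  as.integer(gi == 2L))
      flip <- !is.na(gi) & gi == 1L & stats::runif(m) < 0.5
      tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
      h[2L * i - 1L, ] <- a; h[2L * i, ] <- b
    }
    # conditioning subsets: the haplotypes of the genotypically nearest
    # individuals, fixed across rounds so the "no switch changes"
    # stopping rule can trigger
    n_cond <- max(1L, params$phase_states %/% 2L)
    Dm <- cross_mean_absdiff(g, g)
    cond <- lapply(seq_len(n), function(i) {
      d <- Dm[i, ]; d[i] <- Inf
      sel <- order(d, seq_len(n))[seq_len(min(n_cond, n - 1L))]
      sort(as.vector(rbind(2L * sel - 1L, 2L * sel)))
    })
    for (r in seq_len(params$phase_rounds_max)) {
      changed <- 0L
      for (i in seq_len(n)) {
        other <- cond[[i]]
        ph <- phase_diploid(g[i, ], h[other, , drop = FALSE], cm,
                            ne = params$ne, theta = params$theta)
        het <- !is.na(g[i, ]) & g[i, ] == 1L
        changed <- changed + sum(ph$h1[het] != h[2L * i - 1L, het])
        h[2L * i - 1L, ] <- ph$h1
        h[2L * i, ] <- ph$h2
      }
      if (r >= params$phase_rounds_min && changed == 0L) break
    }
    hap_set(ds$sites, ds$individuals, h)
  })
}

#' Dosage-result container
#'
#' @param sites site table of the imputed (reference) site list.
#' @param individuals individual table.
#' @param p0,p1,p2 probability matrices (individuals x sites) for 0/1/2
#'   copies of allele 1.
#' @param info optional per-site Info scores.
#' @param validate check that triples sum to one.
#' @return a `dosage_result` with `dosage = p1 + 2 p2`.
#' @export
dosage_result <- function(sites, individuals, p0, p1, p2, info = NULL,
                          validate = TRUE) {
  if (validate) {
    ssum <- p0 + p1 + p2
    if (any(abs(ssum - 1) > 1e-6))
      stop("probability triples must sum to 1")
  }
  structure(list(sites = sites, individuals = individuals,
                 p0 = p0, p1 = p1, p2 = p2,
                 dosage = p1 + 2 * p2, info = info),
            class = "dosage_result")
}

#' @export
print.dosage_result <- function(x, ...) {
  cat(sprintf("<dosage_result> %d individuals x %d sites\n",
              nrow(x$p0), ncol(x$p0)))
  invisible(x)
}

#' Impute a study set against a phased reference panel
#'
#' Per individual and per window: diploid phasing of the typed genotypes
#' against the panel, then haploid copying-model imputation of each
#' haplotype; the two independent allele posteriors combine into genotype
#' probability triples.  Windows of `window_bp` with `overlap_bp` buffers
#' are stitched by assigning each site to the window whose center is
#' nearest.  Typed sites retain their observed genotypes as certainty-1
#' triples unless listed in `masked_sites`.
#'
#' @param study a single-chromosome `geno_ds` whose sites are a subset of
#'   the reference sites (same orientation).
#' @param reference a phased [hap_set()].
#' @param map a `genetic_map`.
#' @param params a [model_params()].
#' @param masked_sites site_ids (in the reference site list) to treat as
#'   untyped for every individual.
#' @return a `dosage_result` over the reference site list, with Info.
#' @export
impute_dataset <- function(study, reference, map, params = model_params(),
                           masked_sites = NULL) {
  ref_sites <- reference$sites
  key_r <- paste(ref_sites$chrom, ref_sites$pos)
  key_s <- paste(study$sites$chrom, study$sites$pos)
  t_idx <- match(key_s, key_r)
  if (anyNA(t_idx)) stop("study sites must be a subset of reference sites")
  G <- study$genotypes
  # align allele-1 identity where letters are transposed
  a_s <- study$sites$allele_a; b_s <- study$sites$allele_b
  a_r <- ref_sites$allele_a[t_idx]; b_r <- ref_sites$allele_b[t_idx]
  transposed <- !is.na(a_s) & !is.na(b_s) & !is.na(a_r) & !is.na(b_r) &
                a_s == b_r & b_s == a_r
  G[, transposed] <- 2L - G[, transposed, drop = FALSE]

  M <- nrow(ref_sites); N <- nrow(G)
  o <- order(t_idx); t_idx <- t_idx[o]; G <- G[, o, drop = FALSE]
  cm <- interpolate_cm(map, ref_sites$pos)
  H <- reference$haplotypes
  K <- nrow(H)

  typed_flag <- rep(FALSE, M); typed_flag[t_idx] <- TRUE
  masked_flag <- rep(FALSE, M)
  if (!is.null(masked_sites))
    masked_flag[match(masked_sites, ref_sites$site_id)] <- TRUE
  use_typed <- typed_flag & !masked_flag

  # phasing conditions on the haplotypes of the panel individuals nearest
  # each study individual at the typed sites (deterministic)
  ref_n <- nrow(reference$individuals)
  n_cond <- max(1L, params$phase_states %/% 2L)
  cond_rows <- if (2L * n_cond >= 2L * ref_n) {
    rep(list(seq_len(K)), N)
  } else {
    Gr <- H[seq(1L, 2L * ref_n, 2L), t_idx, drop = FALSE] +
          H[seq(2L, 2L * ref_n, 2L), t_idx, drop = FALSE]
    Dm <- cross_mean_absdiff(G, Gr)
    lapply(seq_len(N), function(i) {
      sel <- order(Dm[i, ], seq_len(ref_n))[seq_len(min(n_cond, ref_n))]
      sort(as.vector(rbind(2L * sel - 1L, 2L * sel)))
    })
  }

  wins <- plan_windows(ref_sites$pos, params$window_bp, params$overlap_bp)
  site_win <- attr(wins, "assign")
  p0 <- p1 <- p2 <- matrix(0, N, M)
  for (w in seq_len(nrow(wins))) {
    ws <- which(ref_sites$pos >= wins$start[w] & ref_sites$pos < wins$end[w])
    assign_w <- site_win[ws] == w
    if (!any(assign_w)) next
    tw <- which(use_typed[ws])                 # typed positions within window
    Hw <- H[, ws, drop = FALSE]
    cmw <- cm[ws]
    col_of <- match(ws[tw], t_idx)             # study columns for window-typed
    for (i in seq_len(N)) {
      gi <- G[i, col_of]
      if (length(tw) >= 1L && any(!is.na(gi))) {
        ph <- phase_diploid(gi, Hw[cond_rows[[i]], tw, drop = FALSE], cmw[tw],
                            ne = params$ne, theta = params$theta)
        q1 <- impute_haploid(ph$h1, tw, Hw, cmw, ne = params$ne,
                             theta = params$theta)$q
        q2 <- impute_haploid(ph$h2, tw, Hw, cmw, ne = params$ne,
                             theta = params$theta)$q
      } else {
        q1 <- q2 <- colMeans(Hw)
      }
      p2w <- q1 * q2
      p1w <- q1 * (1 - q2) + q2 * (1 - q1)
      p0w <- (1 - q1) * (1 - q2)
      sel <- ws[assign_w]
      p0[i, sel] <- p0w[assign_w]
      p1[i, sel] <- p1w[assign_w]
      p2[i, sel] <- p2w[assign_w]
    }
  }
  # observed typed genotypes stay as certainty-1 triples
  for (j in seq_along(t_idx)) {
    site <- t_idx[j]
    if (!use_typed[site]) next
    gi <- G[, j]
    ok <- !is.na(gi)
    p0[ok, site] <- as.numeric(gi[ok] == 0L)
    p1[ok, site] <- as.numeric(gi[ok] == 1L)
    p2[ok, site] <- as.numeric(gi[ok] == 2L)
  }
  info <- info_score(p0, p1, p2)
  res <- dosage_result(ref_sites, study$individuals, p0, p1, p2,
                       info = info$info)
  res$theta_hat <- info$theta_hat
  res$typed <- use_typed
  res
}

# Window layout: starts step by window_bp - overlap_bp; each site is
# assigned (stitched) to the window with the nearest center.  Returns a
# data.frame of window start/end with a per-site "assign" attribute.
plan_windows <- function(pos, window_bp, overlap_bp) {
  lo <- min(pos); hi <- max(pos)
  if (hi - lo <= window_bp) {
    return(structure(data.frame(start = lo, end = hi + 1),
                     assign = rep(1L, length(pos))))
  }
  step <- window_bp - overlap_bp
  starts <- seq(lo, hi, by = step)
  starts <- starts[starts + overlap_bp < hi]   # last window absorbs the tail
  ends <- pmin(starts + window_bp, hi + 1)
  ends[length(ends)] <- hi + 1
  # stitch at the midpoints of adjacent overlaps: every site then lies
  # inside the window it is assigned to
  cuts <- (starts[-1] + ends[-length(ends)]) / 2
  assign <- findInterval(pos, cuts) + 1L
  structure(data.frame(start = starts, end = ends), assign = assign)
}

#' Per-site Info certainty score
#'
#' Ratio-of-variances certainty metric for imputed genotype probability
#' triples: with per-individual dosage `e = p1 + 2 p2` and second moment
#' `f = p1 + 4 p2`, and estimated allele frequency `theta = sum(e) / 2N`,
#' `info = 1 - sum(f - e^2) / (2 N theta (1 - theta))`, defined as 1 when
#' `theta` is 0 or 1 (a fully certain monomorphic expectation).
#'
#' @param p0,p1,p2 probability matrices (individuals x sites) or vectors
#'   for a single site.
#' @return list: `info`, `theta_hat` (expected allele-1 frequency), per site.
#' @export
info_score <- function(p0, p1, p2) {
  if (is.null(dim(p1))) {
    p0 <- matrix(p0, ncol = 1); p1 <- matrix(p1, ncol = 1)
    p2 <- matrix(p2, ncol = 1)
  }
  n <- nrow(p1)
  e <- p1 + 2 * p2
  f <- p1 + 4 * p2
  theta <- colSums(e) / (2 * n)
  denom <- 2 * n * theta * (1 - theta)
  num <- colSums(f - e^2)
  info <- ifelse(denom <= 0, 1, 1 - num / denom)
  info[theta <= 0 | theta >= 1] <- 1
  list(info = as.numeric(info), theta_hat = as.numeric(theta))
}
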