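# Independent brute-force oracles used to verify the analytic machinery.
# These deliberately use naive formulations (full enumeration, explicit
# transition matrices, plain factorials) so they share no code path with
# the implementations they check.

# Exact Hardy-Weinberg p by full enumeration of the Levene-Haldane
# conditional distribution, with masses computed from plain factorials.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  n_min <- min(n_a, n_b)
  if (n_min == 0) return(1)
  hs <- seq(n_min %% 2, n_min, by = 2)
  w <- vapply(hs, function(h) {
    2^h / (factorial((n_a - h) / 2) * factorial(h) * factorial((n_b - h) / 2))
  }, numeric(1))
  p <- w / sum(w)
  p_obs <- p[match(n_ab, hs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

# Explicit K x K transition matrix of the haploid copying model.
ls_transition_matrix <- function(s, K) {
  matrix(s / K, K, K) + diag(rep(1 - s, K))
}

# Haploid copying-model posteriors by full path enumeration over ALL
# sites (emission 1 at untyped sites).  Returns the per-site allele-1
# posterior and the total likelihood.
oracle_haploid_posthoc <- function(obs, typed_idx, ref, cm, ne, theta = NULL) {
  K <- nrow(ref); M <- ncol(ref)
  lambda <- miscopy_lambda(K, theta)
  d <- diff(cm) / 100
  s <- 1 - exp(-4 * ne * d / K)
  E <- matrix(1, M, K)
  for (t in seq_along(typed_idx)) {
    if (is.na(obs[t])) next
    j <- typed_idx[t]
    E[j, ] <- ifelse(ref[, j] == obs[t], 1 - lambda, lambda)
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), M)))
  q_num <- numeric(M); total <- 0
  for (r in seq_len(nrow(paths))) {
    st <- as.integer(paths[r, ])
    pr <- 1 / K * E[1, st[1]]
    if (M > 1) for (j in 2:M) {
      A <- ls_transition_matrix(s[j - 1], K)
      pr <- pr * A[st[j - 1], st[j]] * E[j, st[j]]
    }
    total <- total + pr
    al <- ref[cbind(st, seq_len(M))]
    q_num <- q_num + pr * al
  }
  list(q = q_num / total, lik = total)
}

# Diploid Viterbi by dynamic programming over the explicit K^2 x K^2
# transition matrix (independent of the case-decomposed implementation).
oracle_diploid_viterbi <- function(g, ref, cm, ne, theta = NULL) {
  K <- nrow(ref); Tn <- length(g)
  lambda <- miscopy_lambda(K, theta)
  d <- diff(cm) / 100
  s <- 1 - exp(-4 * ne * d / K)
  m <- function(b, a) ifelse(b == a, 1 - lambda, lambda)
  emis <- function(gt, a1, a2) {
    if (is.na(gt)) return(1)
    if (gt == 0) m(0, a1) * m(0, a2)
    else if (gt == 2) m(1, a1) * m(1, a2)
    else m(1, a1) * m(0, a2) + m(0, a1) * m(1, a2)
  }
  states <- expand.grid(k1 = seq_len(K), k2 = seq_len(K))
  S <- nrow(states)
  V <- sapply(seq_len(S), function(i)
    log(1 / K^2) + log(emis(g[1], ref[states$k1[i], 1], ref[states$k2[i], 1])))
  back <- matrix(0L, Tn, S)
  for (t in 2:Tn) {
    if (Tn < 2) break
    A1 <- ls_transition_matrix(s[t - 1], K)
    Vn <- numeric(S)
    for (j in seq_len(S)) {
      tr <- log(A1[states$k1, states$k1[j]]) + log(A1[states$k2, states$k2[j]])
      cand <- V + tr
      b <- which.max(cand)        # first maximum: lowest linear index
      back[t, j] <- b
      Vn[j] <- cand[b] +
        log(emis(g[t], ref[states$k1[j], t], ref[states$k2[j], t]))
    }
    V <- Vn
  }
  end <- which.max(V)
  path <- integer(Tn); path[Tn] <- end
  if (Tn > 1) for (t in Tn:2) path[t - 1] <- back[t, path[t]]
  list(score = max(V),
       k1 = states$k1[path], k2 = states$k2[path])
}

# Score an arbitrary diploid state path under the same model (used to
# check that an implementation path attains the oracle optimum).
oracle_diploid_path_score <- function(g, ref, cm, ne, k1, k2, theta = NULL) {
  K <- nrow(ref); Tn <- length(g)
  lambda <- miscopy_lambda(K, theta)
  d <- diff(cm) / 100
  s <- 1 - exp(-4 * ne * d / K)
  m <- function(b, a) ifelse(b == a, 1 - lambda, lambda)
  emis <- function(gt, a1, a2) {
    if (is.na(gt)) return(1)
    if (gt == 0) m(0, a1) * m(0, a2)
    else if (gt == 2) m(1, a1) * m(1, a2)
    else m(1, a1) * m(0, a2) + m(0, a1) * m(1, a2)
  }
  sc <- log(1 / K^2) + log(emis(g[1], ref[k1[1], 1], ref[k2[1], 1]))
  if (Tn > 1) for (t in 2:Tn) {
    A1 <- ls_transition_matrix(s[t - 1], K)
    sc <- sc + log(A1[k1[t - 1], k1[t]]) + log(A1[k2[t - 1], k2[t]]) +
      log(emis(g[t], ref[k1[t], t], ref[k2[t], t]))
  }
  sc
}

# Textbook Pearson correlation (sum formulation), squared.
oracle_r2 <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}
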