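#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Diploid Li-Stephens Viterbi over K x K ordered copying states.
//
// Transitions factorize per haplotype: a(k, j) = s/K + (1 - s) * [k == j],
// which lets each maximization step run in O(K^2) using row/column/global
// maxima of the previous score matrix.  Emissions constrain the unordered
// template-allele sum to the observed genotype with per-haplotype miscopy
// probability lambda.  All scores are log-space.
//
// g:   genotypes at the T typed sites (0/1/2, -1 = missing)
// ref: K x T template alleles (0/1)
// s:   T-1 per-interval switch probabilities
// Returns the most probable state path (1-based template indices) and its
// log score.  Ties resolve deterministically (lowest candidate case, then
// lowest linear state index).
// [[Rcpp::export]]
List diploid_viterbi_cpp(IntegerVector g, IntegerMatrix ref,
                         NumericVector s, double lambda) {
  const int T = g.size();
  const int K = ref.nrow();
  if (K < 1 || T < 1) stop("empty reference or site list");
  if (s.size() != T - 1) stop("switch vector length mismatch");
  const int *refp = INTEGER(ref);

  // emission lookup: le[g][a1][a2]
  double m[2][2];  // m[b][a] = P(observe allele b | template allele a)
  m[0][0] = 1.0 - lambda; m[0][1] = lambda;
  m[1][0] = lambda;       m[1][1] = 1.0 - lambda;
  double le[3][2][2];
  for (int a1 = 0; a1 < 2; ++a1)
    for (int a2 = 0; a2 < 2; ++a2) {
      le[0][a1][a2] = std::log(m[0][a1] * m[0][a2]);
      le[1][a1][a2] = std::log(m[1][a1] * m[0][a2] + m[0][a1] * m[1][a2]);
      le[2][a1][a2] = std::log(m[1][a1] * m[1][a2]);
    }

  std::vector<double> V((size_t)K * K), Vn((size_t)K * K);
  std::vector<unsigned char> cases((size_t)(T > 1 ? T - 1 : 0) * K * K);
  std::vector<int> rowarg((size_t)(T > 1 ? T - 1 : 0) * K);
  std::vector<int> colarg((size_t)(T > 1 ? T - 1 : 0) * K);
  std::vector<int> globarg(T > 1 ? T - 1 : 0);
  std::vector<double> rowmax(K), colmax(K), c3(K);

  {
    const double lprior = -2.0 * std::log((double)K);
    const int *rc = refp;               // column t = 0
    for (int k1 = 0; k1 < K; ++k1) {
      double *Vr = &V[(size_t)k1 * K];
      if (g[0] < 0) {
        for (int k2 = 0; k2 < K; ++k2) Vr[k2] = lprior;
      } else {
        const double e0 = lprior + le[g[0]][rc[k1]][0];
        const double e1 = lprior + le[g[0]][rc[k1]][1];
        for (int k2 = 0; k2 < K; ++k2) Vr[k2] = rc[k2] ? e1 : e0;
      }
    }
  }

  for (int t = 1; t < T; ++t) {
    const double c = s[t - 1] / K;
    const double d = 1.0 - s[t - 1];
    const double lstay = std::log(c + d);
    const double lmove = (c > 0) ? std::log(c) : -INFINITY;
    int *ra = &rowarg[(size_t)(t - 1) * K];
    int *ca = &colarg[(size_t)(t - 1) * K];
    double gmax = -INFINITY; int garg = 0;
    for (int k2 = 0; k2 < K; ++k2) colmax[k2] = -INFINITY;
    for (int k1 = 0; k1 < K; ++k1) {
      const double *Vr = &V[(size_t)k1 * K];
      double rm = -INFINITY; int rj = 0;
      for (int k2 = 0; k2 < K; ++k2) {
        const double v = Vr[k2];
        if (v > rm) { rm = v; rj = k2; }
        if (v > colmax[k2]) { colmax[k2] = v; ca[k2] = k1; }
      }
      rowmax[k1] = rm; ra[k1] = rj;
      if (rm > gmax) { gmax = rm; garg = k1 * K + rj; }
    }
    globarg[t - 1] = garg;

    const double mixed = lstay + lmove;
    const double c4 = gmax + 2.0 * lmove;
    for (int k2 = 0; k2 < K; ++k2) {
      double v = colmax[k2] + mixed;
      c3[k2] = (c4 > v) ? c4 : v;       // pre-merge cases 3 and 4
    }
    unsigned char *cs = &cases[(size_t)(t - 1) * K * K];
    const int *rc = refp + (size_t)K * t;
    const int gt = g[t];
    for (int j1 = 0; j1 < K; ++j1) {
      const double *Vr = &V[(size_t)j1 * K];
      double *Vo = &Vn[(size_t)j1 * K];
      unsigned char *co = cs + (size_t)j1 * K;
      const double c2 = rowmax[j1] + mixed;
      double e01[2] = {0.0, 0.0};
      if (gt >= 0) { e01[0] = le[gt][rc[j1]][0]; e01[1] = le[gt][rc[j1]][1]; }
      for (int j2 = 0; j2 < K; ++j2) {
        double best = Vr[j2] + 2.0 * lstay;
        unsigned char bc = 1;
        if (c2 > best) { best = c2; bc = 2; }
        if (c3[j2] > best) {
          best = c3[j2];
          bc = (colmax[j2] + mixed >= c4) ? 3 : 4;
        }
        Vo[j2] = best + e01[rc[j2]];
        co[j2] = bc;
      }
    }
    std::swap(V, Vn);
  }

  double best = -INFINITY; int bi = 0;
  for (int i = 0; i < K * K; ++i)
    if (V[i] > best) { best = V[i]; bi = i; }

  IntegerVector k1(T), k2(T);
  int p1 = bi / K, p2 = bi % K;
  k1[T - 1] = p1 + 1; k2[T - 1] = p2 + 1;
  for (int t = T - 1; t >= 1; --t) {
    unsigned char bc = cases[(size_t)(t - 1) * K * K + (size_t)p1 * K + p2];
    if (bc == 2) {
      p2 = rowarg[(size_t)(t - 1) * K + p1];
    } else if (bc == 3) {
      p1 = colarg[(size_t)(t - 1) * K + p2];
    } else if (bc == 4) {
      int gi = globarg[t - 1];
      p1 = gi / K; p2 = gi % K;
    }
    k1[t - 1] = p1 + 1; k2[t - 1] = p2 + 1;
  }
  return List::create(_["k1"] = k1, _["k2"] = k2, _["score"] = best);
}
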