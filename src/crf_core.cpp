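// Linear-chain CRF inner loops: forward/backward in log space, Viterbi,
// and the dataset negative log-likelihood with its gradient.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logsumexp(const double* x, int n) {
  double m = x[0];
  for (int i = 1; i < n; ++i) if (x[i] > m) m = x[i];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// alpha recursion; alpha is T*L row-major (alpha[t*L + y])
static void forward_alpha(const std::vector<double>& em,
                          const NumericMatrix& tr, int T, int L,
                          std::vector<double>& alpha) {
  std::vector<double> tmp(L);
  for (int y = 0; y < L; ++y) alpha[y] = em[y];
  for (int t = 1; t < T; ++t) {
    for (int y = 0; y < L; ++y) {
      for (int p = 0; p < L; ++p) tmp[p] = alpha[(t - 1) * L + p] + tr(p, y);
      alpha[t * L + y] = em[t * L + y] + logsumexp(tmp.data(), L);
    }
  }
}

static void backward_beta(const std::vector<double>& em,
                          const NumericMatrix& tr, int T, int L,
                          std::vector<double>& beta) {
  std::vector<double> tmp(L);
  for (int y = 0; y < L; ++y) beta[(T - 1) * L + y] = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int y = 0; y < L; ++y) {
      for (int q = 0; q < L; ++q)
        tmp[q] = tr(y, q) + em[(t + 1) * L + q] + beta[(t + 1) * L + q];
      beta[t * L + y] = logsumexp(tmp.data(), L);
    }
  }
}

// [[Rcpp::export]]
double crf_logZ_cpp(NumericMatrix emission, NumericMatrix transition) {
  int T = emission.nrow(), L = emission.ncol();
  if (T < 1) stop("empty sequence");
  std::vector<double> em(T * L);
  for (int t = 0; t < T; ++t)
    for (int y = 0; y < L; ++y) em[t * L + y] = emission(t, y);
  std::vector<double> alpha(T * L);
  forward_alpha(em, transition, T, L, alpha);
  return logsumexp(alpha.data() + (T - 1) * L, L);
}

// [[Rcpp::export]]
List crf_marginals_cpp(NumericMatrix emission, NumericMatrix transition) {
  int T = emission.nrow(), L = emission.ncol();
  if (T < 1) stop("empty sequence");
  std::vector<double> em(T * L);
  for (int t = 0; t < T; ++t)
    for (int y = 0; y < L; ++y) em[t * L + y] = emission(t, y);
  std::vector<double> alpha(T * L), beta(T * L);
  forward_alpha(em, transition, T, L, alpha);
  backward_beta(em, transition, T, L, beta);
  double logZ = logsumexp(alpha.data() + (T - 1) * L, L);
  NumericMatrix node(T, L);
  for (int t = 0; t < T; ++t)
    for (int y = 0; y < L; ++y)
      node(t, y) = std::exp(alpha[t * L + y] + beta[t * L + y] - logZ);
  NumericMatrix pair(L, L);
  for (int t = 0; t + 1 < T; ++t)
    for (int a = 0; a < L; ++a)
      for (int b = 0; b < L; ++b)
        pair(a, b) += std::exp(alpha[t * L + a] + transition(a, b) +
                               em[(t + 1) * L + b] + beta[(t + 1) * L + b] -
                               logZ);
  return List::create(_["node"] = node, _["pair"] = pair,
                      _["logZ"] = logZ);
}

// MAP decoding; ties broken toward the lower tag index at each step.
// [[Rcpp::export]]
IntegerVector crf_viterbi_cpp(NumericMatrix emission,
                              NumericMatrix transition) {
  int T = emission.nrow(), L = emission.ncol();
  if (T < 1) stop("empty sequence");
  std::vector<double> delta(T * L);
  std::vector<int> psi(T * L, 0);
  for (int y = 0; y < L; ++y) delta[y] = emission(0, y);
  for (int t = 1; t < T; ++t) {
    for (int y = 0; y < L; ++y) {
      double best = delta[(t - 1) * L] + transition(0, y);
      int arg = 0;
      for (int p = 1; p < L; ++p) {
        double v = delta[(t - 1) * L + p] + transition(p, y);
        if (v > best) { best = v; arg = p; }
      }
      delta[t * L + y] = best + emission(t, y);
      psi[t * L + y] = arg;
    }
  }
  int yT = 0;
  double best = delta[(T - 1) * L];
  for (int y = 1; y < L; ++y)
    if (delta[(T - 1) * L + y] > best) { best = delta[(T - 1) * L + y]; yT = y; }
  IntegerVector path(T);
  path[T - 1] = yT + 1;  // 1-based for R
  for (int t = T - 1; t > 0; --t) {
    yT = psi[t * L + yT];
    path[t - 1] = yT + 1;
  }
  return path;
}

// Dataset NLL and gradient. Each element of `seqs` is a list with
//   feats: 0-based feature ids, all positions concatenated
//   offs:  length T+1, 0-based offsets into feats per position
//   gold:  0-based gold tag per position
// W is F x L state weights, Tr is L x L transition weights.
// [[Rcpp::export]]
List crf_obj_cpp(List seqs, NumericMatrix W, NumericMatrix Tr,
                 bool want_grad) {
  int F = W.nrow(), L = W.ncol();
  double nll = 0.0;
  NumericMatrix gW(F, L), gT(L, L);
  int nseq = seqs.size();
  for (int si = 0; si < nseq; ++si) {
    List sq = seqs[si];
    IntegerVector feats = sq["feats"];
    IntegerVector offs = sq["offs"];
    IntegerVector gold = sq["gold"];
    int T = offs.size() - 1;
    if (T < 1) continue;
    std::vector<double> em(T * L, 0.0);
    for (int t = 0; t < T; ++t)
      for (int k = offs[t]; k < offs[t + 1]; ++k) {
        int f = feats[k];
        for (int y = 0; y < L; ++y) em[t * L + y] += W(f, y);
      }
    std::vector<double> alpha(T * L);
    forward_alpha(em, Tr, T, L, alpha);
    double logZ = logsumexp(alpha.data() + (T - 1) * L, L);
    double gs = 0.0;
    for (int t = 0; t < T; ++t) {
      gs += em[t * L + gold[t]];
      if (t > 0) gs += Tr(gold[t - 1], gold[t]);
    }
    nll += logZ - gs;
    if (!want_grad) continue;
    std::vector<double> beta(T * L);
    backward_beta(em, Tr, T, L, beta);
    for (int t = 0; t < T; ++t) {
      for (int y = 0; y < L; ++y) {
        double marg = std::exp(alpha[t * L + y] + beta[t * L + y] - logZ);
        double diff = marg - (gold[t] == y ? 1.0 : 0.0);
        if (diff != 0.0)
          for (int k = offs[t]; k < offs[t + 1]; ++k) gW(feats[k], y) += diff;
      }
      if (t + 1 < T) {
        for (int a = 0; a < L; ++a)
          for (int b = 0; b < L; ++b)
            gT(a, b) += std::exp(alpha[t * L + a] + Tr(a, b) +
                                 em[(t + 1) * L + b] +
                                 beta[(t + 1) * L + b] - logZ);
        gT(gold[t], gold[t + 1]) -= 1.0;
      }
    }
  }
  return List::create(_["nll"] = nll, _["gW"] = gW, _["gT"] = gT);
}
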