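// Linear-chain CRF core: regularized negative log-likelihood + gradient,
// Viterbi decoding and per-position marginals (scaled forward-backward).
//
// Feature matrices arrive as integer id matrices (n_positions x n_templates);
// id 0 means "no feature at this slot" (unknown at decode time), ids are
// otherwise 1-based rows of the weight matrix W (n_features x n_labels).
// First-order label transitions live in Tr (n_labels x n_labels). Probability
// of a path y given observations x:
//   p(y|x) = exp( sum_i e_i(y_i) + sum_i Tr(y_i, y_{i+1}) ) / Z(x)
// with emission e_i(l) = sum over active features f at i of W(f, l).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static void emission_scores(const IntegerMatrix& feats, const NumericMatrix& W,
                            std::vector<double>& E, int L) {
  const int n = feats.nrow(), T = feats.ncol();
  std::fill(E.begin(), E.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < T; ++t) {
      const int f = feats(i, t);
      if (f > 0) {
        const int base = f - 1;
        for (int l = 0; l < L; ++l) E[i * L + l] += W(base, l);
      }
    }
  }
}

// Scaled forward-backward. Returns logZ; fills alpha, beta (scaled) and the
// per-position scaling constants. expE/expT are exp() of scores, shifted per
// position by the max emission for numerical range.
struct FB {
  std::vector<double> alpha, beta, scale, expE, shift;
  double logZ;
};

static void forward_backward(const std::vector<double>& E, int n, int L,
                             const NumericMatrix& Tr, FB& fb) {
  fb.alpha.assign(n * L, 0.0);
  fb.beta.assign(n * L, 0.0);
  fb.scale.assign(n, 0.0);
  fb.expE.assign(n * L, 0.0);
  fb.shift.assign(n, 0.0);
  std::vector<double> expT(L * L);
  for (int a = 0; a < L; ++a)
    for (int b = 0; b < L; ++b) expT[a * L + b] = std::exp(Tr(a, b));
  for (int i = 0; i < n; ++i) {
    double m = E[i * L];
    for (int l = 1; l < L; ++l) m = std::max(m, E[i * L + l]);
    fb.shift[i] = m;
    for (int l = 0; l < L; ++l) fb.expE[i * L + l] = std::exp(E[i * L + l] - m);
  }
  // forward
  double s = 0.0;
  for (int l = 0; l < L; ++l) { fb.alpha[l] = fb.expE[l]; s += fb.alpha[l]; }
  fb.scale[0] = s;
  for (int l = 0; l < L; ++l) fb.alpha[l] /= s;
  for (int i = 1; i < n; ++i) {
    s = 0.0;
    for (int l = 0; l < L; ++l) {
      double acc = 0.0;
      for (int k = 0; k < L; ++k)
        acc += fb.alpha[(i - 1) * L + k] * expT[k * L + l];
      const double v = acc * fb.expE[i * L + l];
      fb.alpha[i * L + l] = v;
      s += v;
    }
    fb.scale[i] = s;
    for (int l = 0; l < L; ++l) fb.alpha[i * L + l] /= s;
  }
  // backward (scaled by the same constants)
  for (int l = 0; l < L; ++l) fb.beta[(n - 1) * L + l] = 1.0;
  for (int i = n - 2; i >= 0; --i) {
    for (int k = 0; k < L; ++k) {
      double acc = 0.0;
      for (int l = 0; l < L; ++l)
        acc += expT[k * L + l] * fb.expE[(i + 1) * L + l] * fb.beta[(i + 1) * L + l];
      fb.beta[i * L + k] = acc / fb.scale[i + 1];
    }
  }
  fb.logZ = 0.0;
  for (int i = 0; i < n; ++i) fb.logZ += std::log(fb.scale[i]) + fb.shift[i];
}

// [[Rcpp::export]]
List crf_nll_grad_cpp(List feats_list, List y_list, NumericMatrix W,
                      NumericMatrix Tr) {
  const int L = W.ncol(), F = W.nrow();
  NumericMatrix gW(F, L), gT(L, L);
  double nll = 0.0;
  FB fb;
  std::vector<double> E;
  std::vector<double> expT(L * L);
  for (int a = 0; a < L; ++a)
    for (int b = 0; b < L; ++b) expT[a * L + b] = std::exp(Tr(a, b));
  const int S = feats_list.size();
  for (int s = 0; s < S; ++s) {
    IntegerMatrix feats = feats_list[s];
    IntegerVector y = y_list[s];
    const int n = feats.nrow(), T = feats.ncol();
    if (n == 0) continue;
    E.assign(n * L, 0.0);
    emission_scores(feats, W, E, L);
    forward_backward(E, n, L, Tr, fb);
    // empirical path score
    double path = E[(0) * L + (y[0] - 1)];
    for (int i = 1; i < n; ++i)
      path += Tr(y[i - 1] - 1, y[i] - 1) + E[i * L + (y[i] - 1)];
    nll += fb.logZ - path;
    // state-feature gradient: marginal - empirical
    for (int i = 0; i < n; ++i) {
      for (int t = 0; t < T; ++t) {
        const int f = feats(i, t);
        if (f <= 0) continue;
        const int base = f - 1;
        for (int l = 0; l < L; ++l)
          gW(base, l) += fb.alpha[i * L + l] * fb.beta[i * L + l];
        gW(base, y[i] - 1) -= 1.0;
      }
    }
    // transition gradient: pairwise marginals - empirical
    for (int i = 0; i + 1 < n; ++i) {
      for (int a = 0; a < L; ++a) {
        const double aa = fb.alpha[i * L + a];
        if (aa == 0.0) continue;
        for (int b = 0; b < L; ++b) {
          const double m = aa * expT[a * L + b] * fb.expE[(i + 1) * L + b] *
            fb.beta[(i + 1) * L + b] / fb.scale[i + 1];
          gT(a, b) += m;
        }
      }
      gT(y[i] - 1, y[i + 1] - 1) -= 1.0;
    }
  }
  return List::create(_["nll"] = nll, _["gW"] = gW, _["gT"] = gT);
}

// [[Rcpp::export]]
List crf_infer_cpp(IntegerMatrix feats, NumericMatrix W, NumericMatrix Tr) {
  const int L = W.ncol();
  const int n = feats.nrow();
  if (n == 0) {
    return List::create(_["path"] = IntegerVector(0),
                        _["marginals"] = NumericMatrix(0, L),
                        _["logZ"] = 0.0, _["log_prob_path"] = 0.0);
  }
  std::vector<double> E(n * L, 0.0);
  emission_scores(feats, W, E, L);
  // Viterbi in log space
  std::vector<double> delta(n * L);
  std::vector<int> psi(n * L, 0);
  for (int l = 0; l < L; ++l) delta[l] = E[l];
  for (int i = 1; i < n; ++i) {
    for (int l = 0; l < L; ++l) {
      double best = delta[(i - 1) * L] + Tr(0, l);
      int arg = 0;
      for (int k = 1; k < L; ++k) {
        const double v = delta[(i - 1) * L + k] + Tr(k, l);
        if (v > best) { best = v; arg = k; }
      }
      delta[i * L + l] = best + E[i * L + l];
      psi[i * L + l] = arg;
    }
  }
  int last = 0;
  double best_score = delta[(n - 1) * L];
  for (int l = 1; l < L; ++l)
    if (delta[(n - 1) * L + l] > best_score) { best_score = delta[(n - 1) * L + l]; last = l; }
  IntegerVector path(n);
  path[n - 1] = last + 1;
  for (int i = n - 1; i > 0; --i) {
    last = psi[i * L + last];
    path[i - 1] = last + 1;
  }
  FB fb;
  forward_backward(E, n, L, Tr, fb);
  NumericMatrix marg(n, L);
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l)
      marg(i, l) = fb.alpha[i * L + l] * fb.beta[i * L + l];
  return List::create(_["path"] = path, _["marginals"] = marg,
                      _["logZ"] = fb.logZ,
                      _["log_prob_path"] = best_score - fb.logZ);
}
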