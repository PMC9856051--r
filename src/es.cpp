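#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted Kolmogorov-Smirnov running-sum statistic over a ranked list.
// hits must be sorted ascending, 1-based positions into `score`.
// The running sum is evaluated only where extrema can occur: at each hit
// (local maximum candidate) and just before each hit (local minimum
// candidate). Ties in |deviation| (within ES_TIE_TOL, catching exact
// rational ties computed through different float paths) break to the
// earliest walk step; candidates arrive in non-decreasing step order, so
// keeping the incumbent unless strictly better implements that rule.
static const double ES_TIE_TOL = 1e-9;

static bool es_core(const NumericVector &score, const int *hits, int n,
                    double weight_p, double *out_es, int *out_peak) {
  const int N = score.size();
  const double miss = 1.0 / (double)(N - n);
  std::vector<double> w(n);
  double W = 0.0;
  for (int i = 0; i < n; ++i) {
    double a = std::fabs(score[hits[i] - 1]);
    w[i] = (weight_p == 1.0) ? a : std::pow(a, weight_p);
    W += w[i];
  }
  if (W <= 0.0) return false; // all member scores zero: ES undefined

  double best = 0.0;
  int best_step = N + 1;
  bool unset = true;
  double cum = 0.0;
  for (int i = 0; i < n; ++i) {
    int p = hits[i];
    // value just before hit i (after step p-1); step 0 is not a walk step
    if (p > 1) {
      double bottom = cum / W - (double)(p - 1 - i) * miss;
      if (unset || std::fabs(bottom) > std::fabs(best) + ES_TIE_TOL) {
        best = bottom;
        best_step = p - 1;
        unset = false;
      }
    }
    cum += w[i];
    double top = cum / W - (double)(p - (i + 1)) * miss;
    if (unset || std::fabs(top) > std::fabs(best) + ES_TIE_TOL) {
      best = top;
      best_step = p;
      unset = false;
    }
  }
  *out_es = best;
  *out_peak = best_step;
  return true;
}

// [[Rcpp::export(name = ".es_stat_cpp")]]
List es_stat_cpp(NumericVector score, IntegerVector hits, double weight_p) {
  int n = hits.size();
  std::vector<int> h(hits.begin(), hits.end());
  std::sort(h.begin(), h.end());
  double es = NA_REAL;
  int peak = NA_INTEGER;
  bool ok = es_core(score, h.data(), n, weight_p, &es, &peak);
  return List::create(_["es"] = ok ? es : NA_REAL,
                      _["peak"] = ok ? peak : NA_INTEGER,
                      _["defined"] = ok);
}

// Null distribution of ES for uniformly drawn member subsets of fixed size.
// Uses R's RNG (partial Fisher-Yates), so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".es_null_cpp")]]
NumericVector es_null_cpp(NumericVector score, int set_size, int nperm,
                          double weight_p) {
  const int N = score.size();
  NumericVector out(nperm);
  std::vector<int> idx(N);
  std::vector<int> draw(set_size);
  for (int i = 0; i < N; ++i) idx[i] = i + 1;
  for (int k = 0; k < nperm; ++k) {
    for (int j = 0; j < set_size; ++j) {
      int r = j + (int)(unif_rand() * (double)(N - j));
      if (r >= N) r = N - 1;
      std::swap(idx[j], idx[r]);
      draw[j] = idx[j];
    }
    std::sort(draw.begin(), draw.end());
    double es = NA_REAL;
    int peak = 0;
    bool ok = es_core(score, draw.data(), set_size, weight_p, &es, &peak);
    out[k] = ok ? es : NA_REAL;
  }
  return out;
}
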