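#include <Rcpp.h>
using namespace Rcpp;

// Pooled autocorrelation of reduced force constants over a set of
// profiles: for each lag L, num = sum over proteins of sum_i k_i k_{i+L},
// den = total number of index pairs at distance L. C(L) = num / den.
// [[Rcpp::export]]
List rigidity_autocorr_cpp(List profiles, IntegerVector lags) {
  const int nl = lags.size();
  NumericVector num(nl);
  NumericVector den(nl);
  for (int p = 0; p < profiles.size(); ++p) {
    NumericVector k = profiles[p];
    const int n = k.size();
    for (int l = 0; l < nl; ++l) {
      const int L = lags[l];
      if (L >= n) continue;
      double acc = 0.0;
      for (int i = 0; i + L < n; ++i) acc += k[i] * k[i + L];
      num[l] += acc;
      den[l] += n - L;
    }
  }
  return List::create(_["num"] = num, _["den"] = den);
}

static double pooled_ratio(const std::vector<std::vector<double> > &ks,
                           const IntegerVector &peak,
                           const IntegerVector &flanks) {
  double peak_sum = 0.0, flank_sum = 0.0;
  for (int pass = 0; pass < 2; ++pass) {
    const IntegerVector &lags = pass == 0 ? peak : flanks;
    double acc_mean = 0.0;
    for (int l = 0; l < lags.size(); ++l) {
      const int L = lags[l];
      double num = 0.0, den = 0.0;
      for (size_t p = 0; p < ks.size(); ++p) {
        const std::vector<double> &k = ks[p];
        const int n = (int)k.size();
        if (L >= n) continue;
        for (int i = 0; i + L < n; ++i) num += k[i] * k[i + L];
        den += n - L;
      }
      acc_mean += den > 0 ? num / den : 0.0;
    }
    if (pass == 0) peak_sum = acc_mean / peak.size();
    else flank_sum = acc_mean / flanks.size();
  }
  return peak_sum / flank_sum;
}

// Null distribution of the peak/flank autocorrelation ratio: each
// shuffle permutes every profile independently (Fisher-Yates driven by
// R's uniform RNG) and recomputes the ratio.
// [[Rcpp::export]]
NumericVector rigidity_null_ratios_cpp(List profiles, IntegerVector peak,
                                       IntegerVector flanks,
                                       int n_shuffles) {
  std::vector<std::vector<double> > ks(profiles.size());
  for (int p = 0; p < profiles.size(); ++p) {
    NumericVector k = profiles[p];
    ks[p] = std::vector<double>(k.begin(), k.end());
  }
  NumericVector out(n_shuffles);
  for (int s = 0; s < n_shuffles; ++s) {
    for (size_t p = 0; p < ks.size(); ++p) {
      std::vector<double> &k = ks[p];
      for (int i = (int)k.size() - 1; i > 0; --i) {
        const int j = (int)(unif_rand() * (i + 1));
        std::swap(k[i], k[j <= i ? j : i]);
      }
    }
    out[s] = pooled_ratio(ks, peak, flanks);
  }
  return out;
}
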