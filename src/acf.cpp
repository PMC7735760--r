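#include <Rcpp.h>
using namespace Rcpp;

// Pairwise-complete lagged Pearson autocorrelation.
// For lag k in 0..nlag-1 correlates x[0..L-k) with x[k..L) over positions
// where both values are observed; lags with fewer than min_n overlapping
// observations (or zero variance in either segment) are NA.
// [[Rcpp::export(name = ".acf_nan")]]
List acf_nan(NumericVector x, int nlag, int min_n) {
  int L = x.size();
  NumericVector val(nlag, NA_REAL);
  IntegerVector nused(nlag, 0);
  for (int k = 0; k < nlag; ++k) {
    double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
    int n = 0;
    for (int i = 0; i + k < L; ++i) {
      double a = x[i], b = x[i + k];
      if (ISNAN(a) || ISNAN(b)) continue;
      sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
      ++n;
    }
    nused[k] = n;
    if (n < min_n) continue;
    double va = saa - sa * sa / n;
    double vb = sbb - sb * sb / n;
    if (va <= 0 || vb <= 0) continue;
    val[k] = (sab - sa * sb / n) / std::sqrt(va * vb);
  }
  return List::create(_["values"] = val, _["n_used"] = nused);
}
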