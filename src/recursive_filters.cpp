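#include <Rcpp.h>
using namespace Rcpp;

// Direction-dependent exponential smoothing. Falling samples
// (x[n] - x[n-1] < 0) are tracked with weight alpha on the new sample;
// rising samples (including ties) with weight 1 - alpha. The branch is
// decided on the *input* difference, so the coefficient sequence depends
// only on x, not on the filter state.
// [[Rcpp::export]]
NumericVector cond_ema_cpp(NumericVector x, double alpha) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  if (n == 0) return y;
  y[0] = x[0];
  for (R_xlen_t i = 1; i < n; ++i) {
    double a = (x[i] - x[i - 1] < 0.0) ? alpha : 1.0 - alpha;
    y[i] = a * x[i] + (1.0 - a) * y[i - 1];
  }
  return y;
}

// Dropping counter over one window: the first sample is the reference;
// count samples strictly below it; track the deepest drop (initialised
// at 0); zero the count unless the deepest drop reaches th.
static inline int dcount_one(const double *w, int wlen, double th) {
  int count = 0;
  double dmax = 0.0;
  for (int i = 0; i < wlen; ++i) {
    double d = w[i] - w[0];
    if (d < 0.0) {
      ++count;
      if (d < dmax) dmax = d;
    }
  }
  if (dmax > th) count = 0;
  return count;
}

// Sliding application at stride 1: counts[n] belongs to reference index n.
// [[Rcpp::export]]
IntegerVector d_counter_cpp(NumericVector x, int w, double th) {
  R_xlen_t n = x.size();
  R_xlen_t m = n - w + 1;
  IntegerVector out(m);
  const double *px = REAL(x);
  for (R_xlen_t i = 0; i < m; ++i)
    out[i] = dcount_one(px + i, w, th);
  return out;
}
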