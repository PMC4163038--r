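#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of response-conditional confidence counts under the
// equal-variance Gaussian meta-d' model.
//
// par    : meta_d, then K-1 log-increments for the S1-side type-2 criteria
//          (descending away from the type-1 criterion), then K-1
//          log-increments for the S2 side (ascending).
// counts : 4 x K matrix, rows S1_correct, S1_incorrect, S2_correct,
//          S2_incorrect; columns are confidence bins (low -> high).
// cprime : relative type-1 criterion c/d'; the model's criterion is held at
//          meta_c = cprime * meta_d.
//
// The likelihood is multinomial over confidence bins conditional on the
// response, with evidence ~ N(-meta_d/2, 1) for S1 stimuli and
// N(+meta_d/2, 1) for S2 stimuli.
// [[Rcpp::export]]
double type2_nll_cpp(NumericVector par, NumericMatrix counts, double cprime) {
  const int K = counts.ncol();
  const double md = par[0];
  const double mc = cprime * md;
  const double floor_p = 1e-12;

  std::vector<double> tS1(K - 1), tS2(K - 1);
  double lo = mc, hi = mc;
  for (int j = 0; j < K - 1; ++j) {
    lo -= std::exp(par[1 + j]);
    hi += std::exp(par[K + j]);
    tS1[j] = lo;
    tS2[j] = hi;
  }

  double ll = 0.0;
  for (int s = 0; s < 2; ++s) {  // 0 = S1 stimulus, 1 = S2 stimulus
    const double mu = (s == 0) ? -md / 2.0 : md / 2.0;
    const double pS2resp = std::max(R::pnorm(mu - mc, 0.0, 1.0, 1, 0), floor_p);
    const double pS1resp = std::max(1.0 - R::pnorm(mu - mc, 0.0, 1.0, 1, 0), floor_p);
    // rows: counts for this stimulus under each response
    const int rowS1 = (s == 0) ? 0 : 1;  // S1 resp: correct if s==S1 else incorrect
    const int rowS2 = (s == 1) ? 2 : 3;  // S2 resp: correct if s==S2 else incorrect

    // response S2: bins partition (mc, Inf) at tS2
    double upper_prev = R::pnorm(mu - mc, 0.0, 1.0, 1, 0);  // P(x > mc)
    for (int b = 0; b < K; ++b) {
      double upper = (b < K - 1) ? R::pnorm(mu - tS2[b], 0.0, 1.0, 1, 0) : 0.0;
      double p = std::max((upper_prev - upper) / pS2resp, floor_p);
      ll += counts(rowS2, b) * std::log(p);
      upper_prev = upper;
    }
    // response S1: bins partition (-Inf, mc) at tS1, confidence increasing
    // away from mc
    double lower_prev = R::pnorm(mc - mu, 0.0, 1.0, 1, 0);  // P(x < mc)
    for (int b = 0; b < K; ++b) {
      double lower = (b < K - 1) ? R::pnorm(tS1[b] - mu, 0.0, 1.0, 1, 0) : 0.0;
      double p = std::max((lower_prev - lower) / pS1resp, floor_p);
      ll += counts(rowS1, b) * std::log(p);
      lower_prev = lower;
    }
  }
  return -ll;
}
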