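#include <Rcpp.h>
using namespace Rcpp;

// Systematic-scan Gibbs sampler for the autologistic binary field.
// Full conditional: logit P(y_i = 1 | y_-i) = eta_i + gamma * A_i(y_-i),
// where A_i is the inverse-distance-normalized average of neighbour states.
// Neighbour structure arrives in compressed-column layout (nb_ptr, nb_idx,
// nb_w) taken from the symmetric sparse weight matrix; w_sum[i] is the
// weight total of unit i. Isolated units (w_sum == 0) fall back to the
// current prevalence among the other units, mirroring autocovariate().
// Uses R's RNG so set.seed() in R governs reproducibility.
// [[Rcpp::export]]
IntegerVector gibbs_autologistic_cpp(NumericVector eta, double gamma,
                                     IntegerVector nb_ptr,
                                     IntegerVector nb_idx,
                                     NumericVector nb_w,
                                     NumericVector w_sum,
                                     IntegerVector y_init, int sweeps) {
  int n = eta.size();
  IntegerVector y = clone(y_init);
  double ysum = 0.0;
  for (int i = 0; i < n; i++) ysum += y[i];
  RNGScope scope;
  for (int s = 0; s < sweeps; s++) {
    for (int i = 0; i < n; i++) {
      double ac;
      if (w_sum[i] > 0.0) {
        double acc = 0.0;
        for (int k = nb_ptr[i]; k < nb_ptr[i + 1]; k++) {
          acc += nb_w[k] * y[nb_idx[k]];
        }
        ac = acc / w_sum[i];
      } else {
        ac = (n > 1) ? (ysum - y[i]) / (n - 1.0) : 0.0;
      }
      double lp = eta[i] + gamma * ac;
      double p = 1.0 / (1.0 + std::exp(-lp));
      int ynew = (unif_rand() < p) ? 1 : 0;
      ysum += ynew - y[i];
      y[i] = ynew;
    }
  }
  return y;
}
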