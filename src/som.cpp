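#include <Rcpp.h>
using namespace Rcpp;

// Online training of a one-dimensional chain of k SOM nodes.
//
// x:     G x D matrix of gene profiles
// order: E x G matrix of 1-based gene indices, one row per epoch, giving the
//        presentation order (generated in R so that reproducibility is
//        controlled by R's RNG alone)
// init:  k x D initial node weights
// The learning rate decays linearly from alpha0 to alpha1 and the Gaussian
// neighbourhood radius from sigma0 to sigma1 over all presentations.
// Returns the 1-based index of each gene's best-matching node after training.
// [[Rcpp::export]]
IntegerVector som_chain_train(NumericMatrix x, int k, IntegerMatrix order,
                              NumericMatrix init,
                              double alpha0, double alpha1,
                              double sigma0, double sigma1) {
  const int G = x.nrow(), D = x.ncol(), E = order.nrow();
  NumericMatrix w = clone(init);
  const double total = (double)E * (double)G;
  double step = 0.0;

  for (int e = 0; e < E; ++e) {
    for (int t = 0; t < G; ++t, step += 1.0) {
      const double frac = (total > 1.0) ? step / (total - 1.0) : 0.0;
      const double alpha = alpha0 + (alpha1 - alpha0) * frac;
      const double sigma = sigma0 + (sigma1 - sigma0) * frac;
      const int g = order(e, t) - 1;

      int best = 0;
      double bestd = R_PosInf;
      for (int j = 0; j < k; ++j) {
        double dsum = 0.0;
        for (int d = 0; d < D; ++d) {
          const double diff = w(j, d) - x(g, d);
          dsum += diff * diff;
        }
        if (dsum < bestd) { bestd = dsum; best = j; }
      }

      const double denom = 2.0 * sigma * sigma;
      for (int j = 0; j < k; ++j) {
        const double node_dist = (double)(j - best);
        const double h = alpha * std::exp(-(node_dist * node_dist) / denom);
        if (h > 1e-12) {
          for (int d = 0; d < D; ++d) {
            w(j, d) += h * (x(g, d) - w(j, d));
          }
        }
      }
    }
  }

  IntegerVector assignment(G);
  for (int g = 0; g < G; ++g) {
    int best = 0;
    double bestd = R_PosInf;
    for (int j = 0; j < k; ++j) {
      double dsum = 0.0;
      for (int d = 0; d < D; ++d) {
        const double diff = w(j, d) - x(g, d);
        dsum += diff * diff;
      }
      if (dsum < bestd) { bestd = dsum; best = j; }
    }
    assignment[g] = best + 1;
  }
  return assignment;
}
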