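#include <Rcpp.h>
using namespace Rcpp;

// Accumulate per-event emission log-probabilities for one dataset.
// blocks: one list per indicator with elements
//   type: 1 = discrete (logP lookup), 2 = gaussian, 3 = poisson
//   y: N*J values (column-major over events)
//   jeff: item dimension of the parameter arrays (1 under MI)
//   discrete: logP ((jeff*S) x M matrix); gaussian: mu, sigma (jeff x S);
//   poisson: log_lambda, lambda (jeff x S) and lgam = lgamma(y + 1)
// [[Rcpp::export(name = ".emission_logprob_cpp")]]
NumericVector emission_logprob_cpp(int N, int J, int S, List blocks) {
  const double half_log2pi = 0.91893853320467274178;
  NumericVector logb(N * J * S);
  int NJ = N * J;
  for (int k = 0; k < blocks.size(); ++k) {
    List blk = blocks[k];
    int type = as<int>(blk["type"]);
    int jeff = as<int>(blk["jeff"]);
    NumericVector y = blk["y"];
    if (type == 1) {
      NumericMatrix logP = blk["logP"];
      for (int s = 0; s < S; ++s) {
        double *out = &logb[0] + (R_xlen_t)NJ * s;
        for (int idx = 0; idx < NJ; ++idx) {
          int j = idx / N;
          int row = (jeff == 1 ? 0 : j) + jeff * s;
          out[idx] += logP(row, (int)y[idx]);
        }
      }
    } else if (type == 2) {
      NumericMatrix mu = blk["mu"], sigma = blk["sigma"];
      for (int s = 0; s < S; ++s) {
        double *out = &logb[0] + (R_xlen_t)NJ * s;
        for (int jj = 0; jj < (jeff == 1 ? 1 : J); ++jj) {
          // under MI one parameter set covers all J items
          int lo = (jeff == 1) ? 0 : jj * N;
          int hi = (jeff == 1) ? NJ : (jj + 1) * N;
          double m = mu(jeff == 1 ? 0 : jj, s);
          double sd = sigma(jeff == 1 ? 0 : jj, s);
          double ls = std::log(sd);
          for (int idx = lo; idx < hi; ++idx) {
            double z = (y[idx] - m) / sd;
            out[idx] += -ls - half_log2pi - 0.5 * z * z;
          }
        }
      }
    } else {
      NumericMatrix loglam = blk["log_lambda"], lam = blk["lambda"];
      NumericVector lgam = blk["lgam"];
      for (int s = 0; s < S; ++s) {
        double *out = &logb[0] + (R_xlen_t)NJ * s;
        for (int jj = 0; jj < (jeff == 1 ? 1 : J); ++jj) {
          int lo = (jeff == 1) ? 0 : jj * N;
          int hi = (jeff == 1) ? NJ : (jj + 1) * N;
          double ll = loglam(jeff == 1 ? 0 : jj, s);
          double lv = lam(jeff == 1 ? 0 : jj, s);
          for (int idx = lo; idx < hi; ++idx)
            out[idx] += y[idx] * ll - lv - lgam[idx];
        }
      }
    }
  }
  logb.attr("dim") = IntegerVector::create(N, J, S);
  return logb;
}

// Expected category counts for a discrete indicator: counts[jeff, s, m]
// = sum over subject-events with observed category m of gamma, pooled over
// items when jeff = 1.
// [[Rcpp::export(name = ".expected_counts_cpp")]]
NumericVector expected_counts_cpp(IntegerVector y, NumericVector gamma,
                                  int N, int J, int S, int M, int jeff) {
  NumericVector counts(jeff * S * M);
  int NJ = N * J;
  for (int s = 0; s < S; ++s) {
    const double *g = &gamma[0] + (R_xlen_t)NJ * s;
    for (int idx = 0; idx < NJ; ++idx) {
      int j = idx / N;
      int jj = (jeff == 1) ? 0 : j;
      counts[jj + jeff * s + jeff * S * y[idx]] += g[idx];
    }
  }
  counts.attr("dim") = IntegerVector::create(jeff, S, M);
  return counts;
}
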