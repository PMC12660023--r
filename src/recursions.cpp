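#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over all subjects.
//
// logb: N x J x S array of per-event emission log-probabilities.
// Scaling: at each (i, j) the emission column max m_ij is factored out before
// exponentiation, and the forward normalizer c_ij absorbs the rest, so that
// log scale_ij = log(c_ij) + m_ij and loglik_i = sum_j log scale_ij.
// Returned alpha/beta are the scaled tables; gamma rows sum to one exactly.
// With full = false only gamma, the summed pairwise posteriors (xi_sum) and
// the log-likelihoods are returned -- all the EM update needs -- which avoids
// materializing the N x (J-1) x S x S table.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericVector logb, int N, int J, int S,
            NumericVector pi, NumericMatrix A, bool full) {
  NumericVector gamma(N * J * S);
  NumericVector alpha(full ? N * J * S : 0), beta(full ? N * J * S : 0);
  NumericMatrix log_scale(full ? N : 1, full ? J : 1);
  NumericVector xi(full && J > 1 ? N * (J - 1) * S * S : 0);
  NumericMatrix xi_sum(S, S);
  NumericVector loglik(N);
  std::vector<double> b(J * S), a_loc(J * S), b_loc(J * S), m(J), ls(J),
      tmp(S);

  for (int i = 0; i < N; ++i) {
    // emission max-shifted exp table for this subject
    for (int j = 0; j < J; ++j) {
      double mx = R_NegInf;
      for (int s = 0; s < S; ++s) {
        double v = logb[i + N * j + N * J * s];
        if (v > mx) mx = v;
      }
      if (!R_finite(mx))
        stop("all-zero emission probabilities for subject %d at event %d",
             i + 1, j + 1);
      m[j] = mx;
      for (int s = 0; s < S; ++s)
        b[j + J * s] = std::exp(logb[i + N * j + N * J * s] - mx);
    }
    // forward
    double ll = 0.0;
    for (int j = 0; j < J; ++j) {
      double c = 0.0;
      for (int s = 0; s < S; ++s) {
        double a;
        if (j == 0) {
          a = pi[s] * b[0 + J * s];
        } else {
          double acc = 0.0;
          for (int r = 0; r < S; ++r) acc += a_loc[(j - 1) + J * r] * A(r, s);
          a = acc * b[j + J * s];
        }
        tmp[s] = a;
        c += a;
      }
      if (!(c > 0.0) || !R_finite(c))
        stop("forward normalizer vanished for subject %d at event %d",
             i + 1, j + 1);
      for (int s = 0; s < S; ++s) a_loc[j + J * s] = tmp[s] / c;
      ls[j] = std::log(c) + m[j];
      ll += ls[j];
    }
    loglik[i] = ll;
    // backward (scaled by the forward normalizers)
    for (int s = 0; s < S; ++s) b_loc[(J - 1) + J * s] = 1.0;
    for (int j = J - 2; j >= 0; --j) {
      double cnext = std::exp(ls[j + 1] - m[j + 1]);
      for (int s = 0; s < S; ++s) {
        double acc = 0.0;
        for (int r = 0; r < S; ++r)
          acc += A(s, r) * b[(j + 1) + J * r] * b_loc[(j + 1) + J * r];
        tmp[s] = acc / cnext;
      }
      for (int s = 0; s < S; ++s) b_loc[j + J * s] = tmp[s];
    }
    // posteriors
    for (int j = 0; j < J; ++j) {
      double tot = 0.0;
      for (int s = 0; s < S; ++s) {
        double g = a_loc[j + J * s] * b_loc[j + J * s];
        tmp[s] = g;
        tot += g;
      }
      if (!(tot > 0.0))
        stop("posterior normalizer vanished for subject %d at event %d",
             i + 1, j + 1);
      for (int s = 0; s < S; ++s)
        gamma[i + N * j + N * J * s] = tmp[s] / tot;
    }
    for (int j = 0; j + 1 < J; ++j) {
      double cnext = std::exp(ls[j + 1] - m[j + 1]);
      for (int s = 0; s < S; ++s) {
        double as = a_loc[j + J * s];
        if (as == 0.0) continue;
        for (int r = 0; r < S; ++r) {
          double v = as * A(s, r) * b[(j + 1) + J * r] *
                     b_loc[(j + 1) + J * r] / cnext;
          xi_sum(s, r) += v;
          if (full)
            xi[i + N * j + N * (J - 1) * s + N * (J - 1) * S * r] = v;
        }
      }
    }
    if (full) {
      for (int j = 0; j < J; ++j) {
        log_scale(i, j) = ls[j];
        for (int s = 0; s < S; ++s) {
          alpha[i + N * j + N * J * s] = a_loc[j + J * s];
          beta[i + N * j + N * J * s] = b_loc[j + J * s];
        }
      }
    }
  }

  gamma.attr("dim") = IntegerVector::create(N, J, S);
  if (full) {
    alpha.attr("dim") = IntegerVector::create(N, J, S);
    beta.attr("dim") = IntegerVector::create(N, J, S);
    if (J > 1) xi.attr("dim") = IntegerVector::create(N, J - 1, S, S);
    return List::create(_["alpha"] = alpha, _["beta"] = beta,
                        _["gamma"] = gamma, _["xi"] = xi,
                        _["xi_sum"] = xi_sum,
                        _["log_scale"] = log_scale, _["loglik"] = loglik);
  }
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                      _["loglik"] = loglik);
}

// Viterbi max-product decoding in log space, ties broken toward the lowest
// state index (strict improvement required to switch backpointer).
// [[Rcpp::export(name = ".viterbi_cpp")]]
List viterbi_cpp(NumericVector logb, int N, int J, int S,
                 NumericVector log_pi, NumericMatrix log_A) {
  IntegerMatrix states(N, J);
  NumericVector log_joint(N);
  std::vector<double> d(J * S);
  std::vector<int> bp(J * S);

  for (int i = 0; i < N; ++i) {
    for (int s = 0; s < S; ++s)
      d[0 + J * s] = log_pi[s] + logb[i + N * 0 + N * J * s];
    for (int j = 1; j < J; ++j) {
      for (int s = 0; s < S; ++s) {
        double best = R_NegInf;
        int arg = 0;
        for (int r = 0; r < S; ++r) {
          double v = d[(j - 1) + J * r] + log_A(r, s);
          if (v > best) { best = v; arg = r; }
        }
        d[j + J * s] = best + logb[i + N * j + N * J * s];
        bp[j + J * s] = arg;
      }
    }
    double best = R_NegInf;
    int arg = 0;
    for (int s = 0; s < S; ++s) {
      if (d[(J - 1) + J * s] > best) { best = d[(J - 1) + J * s]; arg = s; }
    }
    if (!R_finite(best) && best == R_NegInf)
      stop("no admissible state path for subject %d", i + 1);
    log_joint[i] = best;
    states(i, J - 1) = arg + 1;
    for (int j = J - 1; j > 0; --j) {
      arg = bp[j + J * arg];
      states(i, j - 1) = arg + 1;
    }
  }
  return List::create(_["states"] = states, _["log_joint"] = log_joint);
}
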