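// Linear-chain CRF primitives: exact log-partition (forward algorithm in log
// space), Viterbi decoding with deterministic tie-breaking, and
// forward-backward marginals / expected transition counts for training.
//
// Conventions: emissions is T x L (T positions, L labels); transitions is
// (L+2) x (L+2) with rows = from-state, cols = to-state; 0-based state L is
// the start state and L+1 the stop state. Scores may be -inf (masked).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static double logsumexp_vec(const arma::vec& x) {
  double m = x.max();
  if (!std::isfinite(m)) return m; // all -inf (m can't be +inf here)
  return m + std::log(arma::sum(arma::exp(x - m)));
}

// [[Rcpp::export(name = ".crf_log_partition_cpp")]]
double crf_log_partition_cpp(const arma::mat& emissions,
                             const arma::mat& transitions) {
  const int T = emissions.n_rows, L = emissions.n_cols;
  if (T < 1) stop("emissions must have at least one row");
  if ((int)transitions.n_rows != L + 2 || (int)transitions.n_cols != L + 2)
    stop("transitions must be (L+2) x (L+2)");
  if (emissions.has_nan() || transitions.has_nan())
    stop("NaN in CRF inputs");
  const int START = L, STOP = L + 1;
  arma::vec alpha = emissions.row(0).t() + transitions(START, arma::span(0, L - 1)).t();
  arma::vec nxt(L);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < L; ++j) {
      arma::vec v = alpha + transitions(arma::span(0, L - 1), j);
      nxt(j) = logsumexp_vec(v) + emissions(t, j);
    }
    alpha = nxt;
  }
  arma::vec fin = alpha + transitions(arma::span(0, L - 1), STOP);
  return logsumexp_vec(fin);
}

// [[Rcpp::export(name = ".crf_viterbi_cpp")]]
List crf_viterbi_cpp(const arma::mat& emissions, const arma::mat& transitions) {
  const int T = emissions.n_rows, L = emissions.n_cols;
  if (T < 1) stop("emissions must have at least one row");
  if ((int)transitions.n_rows != L + 2 || (int)transitions.n_cols != L + 2)
    stop("transitions must be (L+2) x (L+2)");
  if (emissions.has_nan() || transitions.has_nan())
    stop("NaN in CRF inputs");
  const int START = L, STOP = L + 1;
  arma::mat delta(T, L);
  arma::imat back(T, L, arma::fill::zeros);
  for (int j = 0; j < L; ++j)
    delta(0, j) = emissions(0, j) + transitions(START, j);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < L; ++j) {
      double best = NEG_INF; int arg = 0;
      for (int i = 0; i < L; ++i) { // ascending i + strict '>' => lowest index wins ties
        double s = delta(t - 1, i) + transitions(i, j);
        if (s > best) { best = s; arg = i; }
      }
      delta(t, j) = best + emissions(t, j);
      back(t, j) = arg;
    }
  }
  double best = NEG_INF; int arg = 0;
  for (int j = 0; j < L; ++j) {
    double s = delta(T - 1, j) + transitions(j, STOP);
    if (s > best) { best = s; arg = j; }
  }
  if (!std::isfinite(best)) stop("all label paths have -inf score");
  IntegerVector path(T);
  int cur = arg;
  for (int t = T - 1; t >= 0; --t) {
    path[t] = cur + 1; // 1-based for R
    if (t > 0) cur = back(t, cur);
  }
  return List::create(_["path"] = path, _["score"] = best);
}

// Forward-backward: returns logZ, node marginals (T x L) and expected
// transition counts ((L+2) x (L+2), start/stop rows included).
// [[Rcpp::export(name = ".crf_forward_backward_cpp")]]
List crf_forward_backward_cpp(const arma::mat& emissions,
                              const arma::mat& transitions) {
  const int T = emissions.n_rows, L = emissions.n_cols;
  const int START = L, STOP = L + 1;
  arma::mat alpha(T, L), beta(T, L);
  for (int j = 0; j < L; ++j)
    alpha(0, j) = emissions(0, j) + transitions(START, j);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < L; ++j) {
      arma::vec v = alpha.row(t - 1).t() + transitions(arma::span(0, L - 1), j);
      alpha(t, j) = logsumexp_vec(v) + emissions(t, j);
    }
  for (int j = 0; j < L; ++j)
    beta(T - 1, j) = transitions(j, STOP);
  for (int t = T - 2; t >= 0; --t)
    for (int i = 0; i < L; ++i) {
      arma::vec v = transitions(i, arma::span(0, L - 1)).t()
        + emissions.row(t + 1).t() + beta.row(t + 1).t();
      beta(t, i) = logsumexp_vec(v);
    }
  arma::vec fin = alpha.row(T - 1).t() + transitions(arma::span(0, L - 1), STOP);
  double logZ = logsumexp_vec(fin);

  arma::mat marg(T, L);
  for (int t = 0; t < T; ++t)
    for (int j = 0; j < L; ++j)
      marg(t, j) = std::exp(alpha(t, j) + beta(t, j) - logZ);

  arma::mat etr(L + 2, L + 2, arma::fill::zeros);
  for (int j = 0; j < L; ++j)
    etr(START, j) = std::exp(transitions(START, j) + emissions(0, j) + beta(0, j) - logZ);
  for (int t = 0; t + 1 < T; ++t)
    for (int i = 0; i < L; ++i)
      for (int j = 0; j < L; ++j)
        etr(i, j) += std::exp(alpha(t, i) + transitions(i, j)
                              + emissions(t + 1, j) + beta(t + 1, j) - logZ);
  for (int i = 0; i < L; ++i)
    etr(i, STOP) = std::exp(alpha(T - 1, i) + transitions(i, STOP) - logZ);

  return List::create(_["logZ"] = logZ, _["marginals"] = marg,
                      _["expected_transitions"] = etr);
}
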