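// Log-space dynamic programming core for discrete-alphabet HMMs.
//
// All routines take log parameters (log initial vector, dense log transition
// matrix with -Inf marking structurally disallowed transitions, log emission
// matrix over the 20-letter amino-acid alphabet) and an integer-encoded
// observation vector (0-based letter indices; -1 marks an ambiguous residue,
// emitted with probability 1/20 in every state so that it is class-neutral).
//
// The models have no end state: the forward likelihood sums, and Viterbi
// maximises, over all states at the final position.

#include <Rcpp.h>
#include <vector>
#include <utility>
#include <cmath>

using namespace Rcpp;

static inline double logaddexp(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  if (a < b) std::swap(a, b);
  return a + log1p(exp(b - a));
}

static const double LOG_AMBIG = -std::log(20.0);

static inline double log_emit(const NumericMatrix& logE, int s, int o) {
  return (o < 0) ? LOG_AMBIG : logE(s, o);
}

// Sparse predecessor lists: for each target state j, the states i with a
// structurally allowed transition i -> j, in increasing i (gives the
// lowest-state-index tie-break for free in Viterbi).
static std::vector<std::vector<std::pair<int, double> > >
predecessors(const NumericMatrix& logA) {
  int S = logA.nrow();
  std::vector<std::vector<std::pair<int, double> > > pred(S);
  for (int j = 0; j < S; ++j)
    for (int i = 0; i < S; ++i)
      if (logA(i, j) > R_NegInf)
        pred[j].push_back(std::make_pair(i, logA(i, j)));
  return pred;
}

static std::vector<std::vector<std::pair<int, double> > >
successors(const NumericMatrix& logA) {
  int S = logA.nrow();
  std::vector<std::vector<std::pair<int, double> > > succ(S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j)
      if (logA(i, j) > R_NegInf)
        succ[i].push_back(std::make_pair(j, logA(i, j)));
  return succ;
}

// [[Rcpp::export]]
double forward_loglik_cpp(NumericVector log_init, NumericMatrix log_trans,
                          NumericMatrix log_emis, IntegerVector obs) {
  int S = log_init.size(), L = obs.size();
  std::vector<std::vector<std::pair<int, double> > > pred = predecessors(log_trans);
  std::vector<double> alpha(S), alpha2(S);
  for (int j = 0; j < S; ++j)
    alpha[j] = log_init[j] + log_emit(log_emis, j, obs[0]);
  for (int t = 1; t < L; ++t) {
    for (int j = 0; j < S; ++j) {
      double acc = R_NegInf;
      const std::vector<std::pair<int, double> >& pj = pred[j];
      for (size_t k = 0; k < pj.size(); ++k)
        acc = logaddexp(acc, alpha[pj[k].first] + pj[k].second);
      alpha2[j] = acc + log_emit(log_emis, j, obs[t]);
    }
    alpha.swap(alpha2);
  }
  double ll = R_NegInf;
  for (int j = 0; j < S; ++j) ll = logaddexp(ll, alpha[j]);
  return ll;
}

// [[Rcpp::export]]
List viterbi_cpp(NumericVector log_init, NumericMatrix log_trans,
                 NumericMatrix log_emis, IntegerVector obs) {
  int S = log_init.size(), L = obs.size();
  std::vector<std::vector<std::pair<int, double> > > pred = predecessors(log_trans);
  NumericMatrix delta(L, S);
  IntegerMatrix psi(L, S);
  for (int j = 0; j < S; ++j) {
    delta(0, j) = log_init[j] + log_emit(log_emis, j, obs[0]);
    psi(0, j) = -1;
  }
  for (int t = 1; t < L; ++t) {
    for (int j = 0; j < S; ++j) {
      double best = R_NegInf;
      int arg = -1;
      const std::vector<std::pair<int, double> >& pj = pred[j];
      // predecessors are in increasing state index; strict '>' keeps the
      // lowest-index predecessor on ties
      for (size_t k = 0; k < pj.size(); ++k) {
        double v = delta(t - 1, pj[k].first) + pj[k].second;
        if (v > best) { best = v; arg = pj[k].first; }
      }
      delta(t, j) = best + log_emit(log_emis, j, obs[t]);
      psi(t, j) = arg;
    }
  }
  double best = R_NegInf;
  int last = -1;
  for (int j = 0; j < S; ++j)
    if (delta(L - 1, j) > best) { best = delta(L - 1, j); last = j; }
  IntegerVector path(L);
  if (last < 0 || best == R_NegInf) {
    return List::create(_["path"] = IntegerVector(0), _["logp"] = R_NegInf);
  }
  path[L - 1] = last;
  for (int t = L - 1; t > 0; --t)
    path[t - 1] = psi(t, path[t]);
  return List::create(_["path"] = path, _["logp"] = best);
}

// One Baum-Welch E-step for a single sequence: expected initial-state,
// transition and emission counts plus the forward log-likelihood.
// Ambiguous positions (obs < 0) contribute to occupancy and transitions but
// are excluded from emission counts (their 1/20 emission carries no
// information about any state's emission row).
// [[Rcpp::export]]
List bw_counts_cpp(NumericVector log_init, NumericMatrix log_trans,
                   NumericMatrix log_emis, IntegerVector obs) {
  int S = log_init.size(), L = obs.size(), A = log_emis.ncol();
  std::vector<std::vector<std::pair<int, double> > > pred = predecessors(log_trans);
  std::vector<std::vector<std::pair<int, double> > > succ = successors(log_trans);

  NumericMatrix alpha(L, S), beta(L, S);
  for (int j = 0; j < S; ++j)
    alpha(0, j) = log_init[j] + log_emit(log_emis, j, obs[0]);
  for (int t = 1; t < L; ++t)
    for (int j = 0; j < S; ++j) {
      double acc = R_NegInf;
      const std::vector<std::pair<int, double> >& pj = pred[j];
      for (size_t k = 0; k < pj.size(); ++k)
        acc = logaddexp(acc, alpha(t - 1, pj[k].first) + pj[k].second);
      alpha(t, j) = acc + log_emit(log_emis, j, obs[t]);
    }
  double ll = R_NegInf;
  for (int j = 0; j < S; ++j) ll = logaddexp(ll, alpha(L - 1, j));

  for (int j = 0; j < S; ++j) beta(L - 1, j) = 0.0;
  for (int t = L - 2; t >= 0; --t)
    for (int i = 0; i < S; ++i) {
      double acc = R_NegInf;
      const std::vector<std::pair<int, double> >& si = succ[i];
      for (size_t k = 0; k < si.size(); ++k) {
        int j = si[k].first;
        acc = logaddexp(acc, si[k].second + log_emit(log_emis, j, obs[t + 1]) +
                                 beta(t + 1, j));
      }
      beta(t, i) = acc;
    }

  NumericVector init_counts(S), occupancy(S);
  NumericMatrix trans_counts(S, S), emis_counts(S, A);
  if (ll == R_NegInf)
    return List::create(_["loglik"] = ll, _["init"] = init_counts,
                        _["trans"] = trans_counts, _["emis"] = emis_counts,
                        _["occupancy"] = occupancy);

  for (int t = 0; t < L; ++t)
    for (int j = 0; j < S; ++j) {
      double g = exp(alpha(t, j) + beta(t, j) - ll);
      occupancy[j] += g;
      if (t == 0) init_counts[j] += g;
      if (obs[t] >= 0) emis_counts(j, obs[t]) += g;
    }
  for (int t = 0; t + 1 < L; ++t)
    for (int i = 0; i < S; ++i) {
      const std::vector<std::pair<int, double> >& si = succ[i];
      for (size_t k = 0; k < si.size(); ++k) {
        int j = si[k].first;
        trans_counts(i, j) +=
            exp(alpha(t, i) + si[k].second + log_emit(log_emis, j, obs[t + 1]) +
                beta(t + 1, j) - ll);
      }
    }
  return List::create(_["loglik"] = ll, _["init"] = init_counts,
                      _["trans"] = trans_counts, _["emis"] = emis_counts,
                      _["occupancy"] = occupancy);
}
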