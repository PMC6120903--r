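#include <Rcpp.h>
#include <numeric>
using namespace Rcpp;

// Monte-Carlo exceedance counts for the length-proportional mutation null.
//
// For each of n_samples null worlds, every evolution run r draws m_runs[r]
// distinct sites without replacement with probability proportional to
// `weights` (sequential weighted sampling), and the per-site number of runs
// hit is compared against the observed k_obs.  Uses R's RNG, so results are
// reproducible under set.seed().
//
// [[Rcpp::export(name = ".mc_exceed_counts")]]
IntegerVector mc_exceed_counts(NumericVector weights, IntegerVector m_runs,
                               IntegerVector k_obs, int n_samples) {
  const int n = weights.size();
  const int R = m_runs.size();
  if (k_obs.size() != n) stop("k_obs must have one entry per site");
  for (int r = 0; r < R; ++r) {
    if (m_runs[r] < 0 || m_runs[r] > n)
      stop("a run mutates more sites than exist in the null universe");
  }
  for (int i = 0; i < n; ++i)
    if (!(weights[i] > 0)) stop("site weights must be positive");

  const double wtot0 = std::accumulate(weights.begin(), weights.end(), 0.0);
  std::vector<double> w(n);
  std::vector<int> hits(n);
  std::vector<int> drawn;
  drawn.reserve(n);
  IntegerVector exceed(n);

  RNGScope scope;
  for (int s = 0; s < n_samples; ++s) {
    std::fill(hits.begin(), hits.end(), 0);
    for (int r = 0; r < R; ++r) {
      const int m = m_runs[r];
      if (m == 0) continue;
      std::copy(weights.begin(), weights.end(), w.begin());
      double wtot = wtot0;
      drawn.clear();
      for (int j = 0; j < m; ++j) {
        double u = unif_rand() * wtot;
        double acc = 0.0;
        int pick = -1;
        for (int i = 0; i < n; ++i) {
          if (w[i] <= 0.0) continue;
          acc += w[i];
          pick = i;
          if (u <= acc) break;
        }
        wtot -= w[pick];
        w[pick] = 0.0;
        drawn.push_back(pick);
      }
      for (size_t d = 0; d < drawn.size(); ++d) hits[drawn[d]] += 1;
    }
    for (int i = 0; i < n; ++i)
      if (hits[i] >= k_obs[i]) exceed[i] += 1;
  }
  return exceed;
}
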