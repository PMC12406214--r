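#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Viterbi decoding of the 4-state linear-chain segmentation HMM
// (adapter -> RTA -> poly(A) -> transcript) with minimum state durations
// enforced by state expansion: region i is unrolled into min_dur[i] copies;
// copies 1..m-1 advance deterministically, the terminal copy self-loops with
// probability self_p[i] and hands over to the next region with 1 - self_p[i].
// The last region's terminal copy is absorbing (self log-probability 0), so a
// segmentation's path probability decomposes as
//   sum(emissions) + sum_{i<4} [ (d_i - m_i) log p_i + log(1 - p_i) ]
// which the exhaustive enumeration oracle reproduces independently.
//
// Ties are broken toward the earlier region switch (the cross-region
// predecessor wins on equal score), so decoding is deterministic.
//
// [[Rcpp::export(name = ".viterbi_polya")]]
List viterbi_polya(NumericVector x, NumericVector mean, NumericVector sd,
                   NumericVector self_p, IntegerVector min_dur) {
  const int T = x.size();
  const int R = 4;
  if (mean.size() != R || sd.size() != R || self_p.size() != R ||
      min_dur.size() != R)
    stop("parameters must have length 4");
  std::vector<int> off(R + 1, 0);
  for (int i = 0; i < R; ++i) {
    if (min_dur[i] < 1) stop("minimum durations must be >= 1");
    if (sd[i] <= 0) stop("emission sds must be > 0");
    if (self_p[i] <= 0 || self_p[i] >= 1) stop("self-transitions must be in (0,1)");
    off[i + 1] = off[i] + min_dur[i];
  }
  const int S = off[R];
  if (T < S) stop("signal too short");

  const double NEG = -std::numeric_limits<double>::infinity();
  std::vector<double> lself(R), lswitch(R), lsd(R);
  const double LOG2PI = std::log(2.0 * M_PI);
  for (int i = 0; i < R; ++i) {
    lself[i] = (i == R - 1) ? 0.0 : std::log(self_p[i]);
    lswitch[i] = std::log1p(-self_p[i]);
    lsd[i] = std::log(sd[i]);
  }
  std::vector<int> region(S), copy(S);
  for (int i = 0; i < R; ++i)
    for (int c = 0; c < min_dur[i]; ++c) {
      region[off[i] + c] = i;
      copy[off[i] + c] = c;
    }

  std::vector<double> prev(S, NEG), cur(S, NEG);
  std::vector<int> bp((size_t)T * S, -1);
  std::vector<double> em(R);

  for (int i = 0; i < R; ++i) {
    double z = (x[0] - mean[i]) / sd[i];
    em[i] = -0.5 * LOG2PI - lsd[i] - 0.5 * z * z;
  }
  prev[0] = em[0];

  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < R; ++i) {
      double z = (x[t] - mean[i]) / sd[i];
      em[i] = -0.5 * LOG2PI - lsd[i] - 0.5 * z * z;
    }
    for (int s = 0; s < S; ++s) {
      const int i = region[s], c = copy[s];
      const bool terminal = (c == min_dur[i] - 1);
      double best = NEG;
      int arg = -1;
      // cross-region entry first so it wins ties (earlier switch preferred)
      if (c == 0 && i > 0) {
        double v = prev[off[i] - 1] + lswitch[i - 1];
        if (v > best) { best = v; arg = off[i] - 1; }
      }
      if (c > 0) {
        double v = prev[s - 1];
        if (v > best) { best = v; arg = s - 1; }
      }
      if (terminal) {
        double v = prev[s] + lself[i];
        if (v > best) { best = v; arg = s; }
      }
      cur[s] = (arg < 0) ? NEG : best + em[i];
      bp[(size_t)t * S + s] = arg;
    }
    std::swap(prev, cur);
  }

  // path must end in the transcript region's terminal copy so every region
  // attains its minimum duration
  const int sfinal = S - 1;
  const double logprob = prev[sfinal];
  if (!std::isfinite(logprob)) stop("no feasible segmentation");

  IntegerVector path(T);
  int s = sfinal;
  for (int t = T - 1; t >= 0; --t) {
    path[t] = region[s] + 1;  // 1-based region labels
    if (t > 0) s = bp[(size_t)t * S + s];
  }
  IntegerVector starts(R);   // 0-based start sample of each region
  int seen = 0;
  for (int t = 0; t < T && seen < R; ++t)
    if (path[t] == seen + 1) { starts[seen] = t; ++seen; }

  return List::create(_["starts"] = starts, _["log_prob"] = logprob,
                      _["path"] = path);
}
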