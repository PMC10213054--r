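#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int parity(unsigned int x) {
  return __builtin_popcount(x) & 1;
}

// Shift-register encoder. State holds the last m input bits with the most
// recent at the MSB; the tap window is (bit << m) | state. Appends
// `term_bits` zero flush bits.
// [[Rcpp::export]]
IntegerVector cpp_conv_encode(IntegerVector message, int m, IntegerVector taps,
                              int term_bits) {
  const int S = taps.size();
  const int n = message.size();
  IntegerVector out(S * (n + term_bits));
  unsigned int state = 0;
  const unsigned int smask = (1u << m) - 1u;
  int k = 0;
  for (int t = 0; t < n + term_bits; ++t) {
    const unsigned int bit = (t < n) ? (unsigned int)message[t] : 0u;
    const unsigned int reg = (bit << m) | state;
    for (int s = 0; s < S; ++s) out[k++] = parity(reg & (unsigned int)taps[s]);
    state = (reg >> 1) & smask;
  }
  return out;
}

// Hard-decision Viterbi over the mother-rate stream (erasures coded as -1).
// Zero-tail termination: last m input bits forced to zero; traceback starts
// at state 0. Ties: the smaller predecessor state survives.
// [[Rcpp::export]]
List cpp_viterbi_hard(IntegerVector mother, int m, IntegerVector taps,
                      int n_msg) {
  const int S = taps.size();
  const int steps = mother.size() / S;
  const int nstates = 1 << m;
  const int INF = INT_MAX / 4;
  std::vector<int> metric(nstates, INF), nmetric(nstates);
  std::vector<std::vector<uint16_t> > bp(steps, std::vector<uint16_t>(nstates));
  metric[0] = 0;

  // Precompute per-(state, bit) output bits for each stream.
  std::vector<int> outbits(nstates * 2 * S);
  for (int st = 0; st < nstates; ++st)
    for (int b = 0; b < 2; ++b) {
      unsigned int reg = ((unsigned int)b << m) | (unsigned int)st;
      for (int s = 0; s < S; ++s)
        outbits[(st * 2 + b) * S + s] = parity(reg & (unsigned int)taps[s]);
    }

  for (int t = 0; t < steps; ++t) {
    std::fill(nmetric.begin(), nmetric.end(), INF);
    std::vector<uint16_t>& back = bp[t];
    const int bmax = (t < n_msg) ? 1 : 0; // flush steps force bit 0
    for (int st = 0; st < nstates; ++st) {
      if (metric[st] >= INF) continue;
      for (int b = 0; b <= bmax; ++b) {
        int cost = 0;
        for (int s = 0; s < S; ++s) {
          int r = mother[t * S + s];
          if (r >= 0 && r != outbits[(st * 2 + b) * S + s]) ++cost;
        }
        const int ns = ((b << m) | st) >> 1;
        const int cand = metric[st] + cost;
        // strict < keeps the smaller predecessor on ties (st ascending)
        if (cand < nmetric[ns]) {
          nmetric[ns] = cand;
          back[ns] = (uint16_t)st;
        }
      }
    }
    metric.swap(nmetric);
  }

  IntegerVector msg(n_msg);
  int st = 0; // zero-tail termination ends in state 0
  const int final_metric = metric[0];
  for (int t = steps - 1; t >= 0; --t) {
    const int prev = bp[t][st];
    const int bit = (st >> (m - 1)) & 1; // input bit is the MSB of the state
    if (t < n_msg) msg[t] = bit;
    st = prev;
  }
  return List::create(_["message"] = msg, _["metric"] = final_metric);
}
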