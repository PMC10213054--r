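#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = std::max(a, b);
  return m + std::log1p(std::exp(std::min(a, b) - m));
}

// ---------------------------------------------------------------------------
// Joint (convolutional-code state, base position) list-Viterbi decoding over
// a CTC posterior. Candidate message prefixes live in an arena of
// (parent, new-free-bits) nodes; per trellis state we keep the top-L
// candidates, each with separate blank-ending / nonblank-ending log scores
// merged by logsumexp as paths recombine.
// ---------------------------------------------------------------------------

struct Cand {
  int pref;      // arena node id
  double sb;     // log prob of paths ending in blank
  double snb;    // log prob of paths ending in the last emitted base
};

struct Arena {
  std::vector<int> par;
  std::vector<uint8_t> nfree;
  std::vector<uint8_t> bits;   // packed free bits, first-consumed at MSB
  std::vector<int8_t> last;    // last emitted base 0..3, -1 for root
  int add(int parent, int nf, int b, int lastbase) {
    par.push_back(parent);
    nfree.push_back((uint8_t)nf);
    bits.push_back((uint8_t)b);
    last.push_back((int8_t)lastbase);
    return (int)par.size() - 1;
  }
  std::vector<int> unpack(int id) const {
    std::vector<int> out;
    while (id > 0) {
      for (int i = 0; i < nfree[id]; ++i)
        out.push_back((bits[id] >> i) & 1);  // reversed within node
      id = par[id];
    }
    std::reverse(out.begin(), out.end());
    return out;
  }
};

static bool lex_less(const Arena& ar, int a, int b) {
  std::vector<int> xa = ar.unpack(a), xb = ar.unpack(b);
  return xa < xb;
}

// Dense trellis-state table: one candidate list per (position, node) slot,
// with a touched-list so only active slots are visited and cleared.
struct StateTable {
  std::vector<std::vector<Cand> > slot;
  std::vector<int> touched;
  void init(size_t n) { slot.assign(n, std::vector<Cand>()); }
  void clear() {
    for (size_t i = 0; i < touched.size(); ++i) slot[touched[i]].clear();
    touched.clear();
  }
  void upsert(int key, int pref, double addb, double addnb) {
    std::vector<Cand>& v = slot[key];
    if (v.empty()) touched.push_back(key);
    for (size_t i = 0; i < v.size(); ++i) {
      if (v[i].pref == pref) {
        v[i].sb = lse(v[i].sb, addb);
        v[i].snb = lse(v[i].snb, addnb);
        return;
      }
    }
    Cand c; c.pref = pref; c.sb = addb; c.snb = addnb;
    v.push_back(c);
  }
};

// trellis: list over base positions p = 0..n_pos-1; each element an integer
// matrix with columns (from, to, base, nfree, freebits).
// logpost: T x 5 matrix of log probabilities, columns (blank, A, C, G, T).
// [[Rcpp::export]]
List cpp_ctc_list_decode(NumericMatrix logpost, List trellis, int node_span,
                         int L, int max_active, double prune_margin) {
  const int T = logpost.nrow();
  const int n_pos = trellis.size();

  // Flatten transitions; index by (p, from) via per-position sorted CSR.
  std::vector<int> tr_from, tr_to, tr_base, tr_nfree, tr_bits, tr_p;
  std::vector<std::vector<int> > pos_start(n_pos); // per p: offsets by from
  std::vector<std::vector<int> > pos_order(n_pos);
  for (int p = 0; p < n_pos; ++p) {
    IntegerMatrix m = trellis[p];
    std::vector<int> order(m.nrow());
    for (int i = 0; i < m.nrow(); ++i) order[i] = i;
    std::stable_sort(order.begin(), order.end(),
                     [&](int a, int b) { return m(a, 0) < m(b, 0); });
    std::vector<int> start(node_span + 1, 0);
    for (int i = 0; i < m.nrow(); ++i) start[m(i, 0) + 1]++;
    for (int s = 0; s < node_span; ++s) start[s + 1] += start[s];
    pos_start[p] = start;
    std::vector<int> glob(m.nrow());
    for (int i = 0; i < m.nrow(); ++i) {
      int r = order[i];
      glob[i] = (int)tr_from.size();
      tr_from.push_back(m(r, 0)); tr_to.push_back(m(r, 1));
      tr_base.push_back(m(r, 2)); tr_nfree.push_back(m(r, 3));
      tr_bits.push_back(m(r, 4)); tr_p.push_back(p);
    }
    pos_order[p] = glob;
  }
  std::vector<int> pos_base(n_pos + 1, 0); // global offset of p's block
  for (int p = 0; p < n_pos; ++p)
    pos_base[p + 1] = pos_base[p] + (int)pos_order[p].size();

  Arena ar;
  ar.add(-1, 0, 0, -1); // root = empty prefix
  std::unordered_map<int64_t, int> childmap;

  StateTable cur, nxt;
  const size_t n_slots = (size_t)(n_pos + 1) * node_span;
  cur.init(n_slots);
  nxt.init(n_slots);
  {
    Cand c; c.pref = 0; c.sb = 0.0; c.snb = NEG_INF;
    cur.slot[0].push_back(c); // key = p * node_span + node = 0
    cur.touched.push_back(0);
  }

  for (int t = 0; t < T; ++t) {
    nxt.clear();
    const double lpb = logpost(t, 0);
    const double lp1 = logpost(t, 1), lp2 = logpost(t, 2),
                 lp3 = logpost(t, 3), lp4 = logpost(t, 4);
    const double lpbase[4] = { lp1, lp2, lp3, lp4 };
    for (size_t ti = 0; ti < cur.touched.size(); ++ti) {
      const int key = cur.touched[ti];
      const int p = key / node_span;
      const int node = key % node_span;
      std::vector<Cand>& cands = cur.slot[key];
      for (size_t ci = 0; ci < cands.size(); ++ci) {
        const Cand& c = cands[ci];
        const double tot = lse(c.sb, c.snb);
        // stay: emit blank
        nxt.upsert(key, c.pref, tot + lpb, NEG_INF);
        // stay: repeat the last emitted base (collapses)
        const int lb = ar.last[c.pref];
        if (lb >= 0 && c.snb != NEG_INF)
          nxt.upsert(key, c.pref, NEG_INF, c.snb + lpbase[lb]);
        // extend: one more base of the codeword
        if (p < n_pos) {
          const std::vector<int>& start = pos_start[p];
          for (int k = start[node]; k < start[node + 1]; ++k) {
            const int g = pos_base[p] + k;
            const int b = tr_base[g];
            const double src = (b == lb) ? c.sb : tot;
            if (src == NEG_INF) continue;
            const int64_t ck = ((int64_t)c.pref << 22) | (int64_t)g;
            std::unordered_map<int64_t, int>::iterator f = childmap.find(ck);
            int child;
            if (f == childmap.end()) {
              child = ar.add(c.pref, tr_nfree[g], tr_bits[g], b);
              childmap[ck] = child;
            } else child = f->second;
            const int nkey = (p + 1) * node_span + tr_to[g];
            nxt.upsert(nkey, child, NEG_INF, src + lpbase[b]);
          }
        }
      }
    }
    // prune each state's list to the top L (tie: lexicographically smaller
    // message prefix wins); totals are cached once per step
    double best = NEG_INF;
    size_t total = 0;
    std::vector<double> scores;
    for (size_t ti = 0; ti < nxt.touched.size(); ++ti) {
      std::vector<Cand>& v = nxt.slot[nxt.touched[ti]];
      if (v.empty()) continue;
      std::vector<double> tot(v.size());
      for (size_t i = 0; i < v.size(); ++i) tot[i] = lse(v[i].sb, v[i].snb);
      if ((int)v.size() > L) {
        std::vector<int> ord(v.size());
        for (size_t i = 0; i < v.size(); ++i) ord[i] = (int)i;
        std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
          if (tot[a] != tot[b]) return tot[a] > tot[b];
          return lex_less(ar, v[a].pref, v[b].pref);
        });
        std::vector<Cand> keep(L);
        std::vector<double> ktot(L);
        for (int i = 0; i < L; ++i) { keep[i] = v[ord[i]]; ktot[i] = tot[ord[i]]; }
        v.swap(keep);
        tot.swap(ktot);
      }
      for (size_t i = 0; i < v.size(); ++i) {
        if (tot[i] > best) best = tot[i];
        scores.push_back(tot[i]);
      }
      total += v.size();
    }
    // global pruning: score margin, then a hard cap on active candidates
    double cut = R_finite(prune_margin) ? best - prune_margin : NEG_INF;
    if (max_active > 0 && (int)total > max_active) {
      std::nth_element(scores.begin(), scores.begin() + (max_active - 1),
                       scores.end(), std::greater<double>());
      cut = std::max(cut, scores[max_active - 1]);
    }
    if (cut > NEG_INF) {
      for (size_t ti = 0; ti < nxt.touched.size(); ++ti) {
        std::vector<Cand>& v = nxt.slot[nxt.touched[ti]];
        v.erase(std::remove_if(v.begin(), v.end(), [&](const Cand& c) {
          return lse(c.sb, c.snb) < cut;
        }), v.end());
      }
    }
    cur.slot.swap(nxt.slot);
    cur.touched.swap(nxt.touched);
  }

  // answer: candidates that consumed all n_pos bases and ended in node 0
  std::vector<Cand>& fin = cur.slot[(size_t)n_pos * node_span];
  List msgs;
  NumericVector scores;
  if (!fin.empty()) {
    std::vector<Cand>& v = fin;
    std::stable_sort(v.begin(), v.end(), [&](const Cand& a, const Cand& b) {
      double ta = lse(a.sb, a.snb), tb = lse(b.sb, b.snb);
      if (ta != tb) return ta > tb;
      return lex_less(ar, a.pref, b.pref);
    });
    int n = std::min((int)v.size(), L);
    msgs = List(n);
    scores = NumericVector(n);
    for (int i = 0; i < n; ++i) {
      std::vector<int> bits = ar.unpack(v[i].pref);
      msgs[i] = IntegerVector(bits.begin(), bits.end());
      scores[i] = lse(v[i].sb, v[i].snb);
    }
  }
  return List::create(_["messages"] = msgs, _["log_scores"] = scores);
}

// ---------------------------------------------------------------------------
// Unconstrained CTC prefix beam search (basecalling without a code).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_beam_search(NumericMatrix logpost, int beam_width) {
  const int T = logpost.nrow();
  Arena ar;
  ar.add(-1, 0, 0, -1);
  std::unordered_map<int64_t, int> childmap;
  std::vector<Cand> cur, nxt;
  {
    Cand c; c.pref = 0; c.sb = 0.0; c.snb = NEG_INF;
    cur.push_back(c);
  }
  for (int t = 0; t < T; ++t) {
    std::unordered_map<int, int> where; // pref -> index in nxt
    nxt.clear();
    const double lpb = logpost(t, 0);
    for (size_t ci = 0; ci < cur.size(); ++ci) {
      const Cand& c = cur[ci];
      const double tot = lse(c.sb, c.snb);
      const int lb = ar.last[c.pref];
      // blank keeps the prefix
      {
        std::unordered_map<int, int>::iterator f = where.find(c.pref);
        if (f == where.end()) {
          Cand nc; nc.pref = c.pref; nc.sb = tot + lpb; nc.snb = NEG_INF;
          where[c.pref] = (int)nxt.size();
          nxt.push_back(nc);
        } else nxt[f->second].sb = lse(nxt[f->second].sb, tot + lpb);
      }
      // repeat last base keeps the prefix
      if (lb >= 0 && c.snb != NEG_INF) {
        double add = c.snb + logpost(t, 1 + lb);
        std::unordered_map<int, int>::iterator f = where.find(c.pref);
        if (f == where.end()) {
          Cand nc; nc.pref = c.pref; nc.sb = NEG_INF; nc.snb = add;
          where[c.pref] = (int)nxt.size();
          nxt.push_back(nc);
        } else nxt[f->second].snb = lse(nxt[f->second].snb, add);
      }
      // extend by each base
      for (int b = 0; b < 4; ++b) {
        const double src = (b == lb) ? c.sb : tot;
        if (src == NEG_INF) continue;
        const int64_t ck = ((int64_t)c.pref << 2) | b;
        std::unordered_map<int64_t, int>::iterator f = childmap.find(ck);
        int child;
        if (f == childmap.end()) {
          child = ar.add(c.pref, 2, b, b); // bits slot reused to store base
          childmap[ck] = child;
        } else child = f->second;
        double add = src + logpost(t, 1 + b);
        std::unordered_map<int, int>::iterator g = where.find(child);
        if (g == where.end()) {
          Cand nc; nc.pref = child; nc.sb = NEG_INF; nc.snb = add;
          where[child] = (int)nxt.size();
          nxt.push_back(nc);
        } else nxt[g->second].snb = lse(nxt[g->second].snb, add);
      }
    }
    std::stable_sort(nxt.begin(), nxt.end(), [&](const Cand& a, const Cand& b) {
      double ta = lse(a.sb, a.snb), tb = lse(b.sb, b.snb);
      if (ta != tb) return ta > tb;
      return lex_less(ar, a.pref, b.pref);
    });
    if ((int)nxt.size() > beam_width) nxt.resize(beam_width);
    cur = nxt;
  }
  const int n = (int)cur.size();
  CharacterVector seqs(n);
  NumericVector scores(n);
  const char* bases = "ACGT";
  for (int i = 0; i < n; ++i) {
    std::string s;
    int id = cur[i].pref;
    while (id > 0) { s.push_back(bases[ar.bits[id]]); id = ar.par[id]; }
    std::reverse(s.begin(), s.end());
    seqs[i] = s;
    scores[i] = lse(cur[i].sb, cur[i].snb);
  }
  return List::create(_["sequences"] = seqs, _["log_probs"] = scores);
}
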