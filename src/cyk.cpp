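// Constrained CYK (Viterbi) and inside dynamic programming over alignment
// column profiles. The chart V[nt][i][j+1] holds the best (or summed)
// log-probability that nonterminal nt derives columns i..j; j = i-1 encodes
// the empty span. Rules are sequences of atoms (single-column emission,
// nonterminal, segment-HMM span), optionally pair-wrapped (the rule emits
// the outermost columns of its span as a base pair). All emission, pair and
// HMM span scores arrive precomputed with constraint masks applied, so the
// kernel is pure max-plus / log-sum-exp algebra.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log1p(std::exp(b - a));
}

struct Engine {
  int n_nt, L, mode; // mode 0 = max, 1 = sum
  const std::vector<double>* V;
  NumericMatrix single_sc;               // tables x L
  std::vector<NumericMatrix> pair_sc;    // L x L each
  std::vector<NumericMatrix> hmm_sc;     // (L+1) x (L+1) each, [i-1][j]
  IntegerVector rule_lhs, rule_pt, rule_na;
  NumericVector rule_lp;
  IntegerMatrix atom_type, atom_ref;

  inline size_t vidx(int nt, int i, int j) const {
    // nt 1-based, i in 1..L+1, j in i-1..L
    return (size_t)(nt - 1) * (L + 1) * (L + 1) +
           (size_t)(i - 1) * (L + 1) + (size_t)j;
  }

  inline double atom_score(int type, int ref, int s, int e) const {
    // atom derives span s..e (e = s-1 empty)
    switch (type) {
      case 1: // emit: exactly one column
        return (e == s) ? single_sc(ref - 1, s - 1) : NEG_INF;
      case 2: // nonterminal
        return (*V)[vidx(ref, s, e)];
      case 3: // segment HMM
        return hmm_sc[ref - 1](s - 1, e);
      default: return NEG_INF;
    }
  }

  // score of rule k deriving span i..j, excluding the rule log-probability
  double rule_body(int k, int i, int j) const {
    int lo = i, hi = j;
    double base = 0.0;
    int pt = rule_pt[k];
    if (pt > 0) {
      if (j < i + 1) return NEG_INF;
      base = pair_sc[pt - 1](i - 1, j - 1);
      if (base == NEG_INF) return NEG_INF;
      lo = i + 1; hi = j - 1;
    }
    int na = rule_na[k];
    if (na == 0) return (hi == lo - 1) ? base : NEG_INF;
    int width = hi - lo + 2; // positions s = lo .. hi+1
    std::vector<double> nxt(width), cur(width);
    for (int w = 0; w < width; ++w) nxt[w] = (lo + w == hi + 1) ? 0.0 : NEG_INF;
    for (int pos = na - 1; pos >= 0; --pos) {
      int type = atom_type(pos, k), ref = atom_ref(pos, k);
      for (int w = 0; w < width; ++w) {
        int s = lo + w;
        double best = NEG_INF;
        if (type == 1) { // emit consumes exactly column s
          if (s <= hi) {
            double a = single_sc(ref - 1, s - 1);
            double rest = nxt[s + 1 - lo];
            if (a != NEG_INF && rest != NEG_INF) best = a + rest;
          }
        } else {
          for (int e = s - 1; e <= hi; ++e) {
            double a = atom_score(type, ref, s, e);
            if (a == NEG_INF) continue;
            double rest = nxt[e + 1 - lo];
            if (rest == NEG_INF) continue;
            double cand = a + rest;
            if (mode == 0) { if (cand > best) best = cand; }
            else best = lse2(best, cand);
          }
        }
        cur[w] = best;
      }
      std::swap(cur, nxt);
    }
    double body = nxt[0];
    return (body == NEG_INF) ? NEG_INF : base + body;
  }
};

// [[Rcpp::export(name = ".cyk_fill")]]
NumericVector cyk_fill(int n_nt, int L,
                       IntegerVector rule_lhs, IntegerVector rule_pt,
                       IntegerVector rule_na, NumericVector rule_lp,
                       IntegerMatrix atom_type, IntegerMatrix atom_ref,
                       IntegerVector topo,
                       NumericMatrix single_sc, List pair_mats, List hmm_mats,
                       int mode) {
  Engine eng;
  eng.n_nt = n_nt; eng.L = L; eng.mode = mode;
  eng.single_sc = single_sc;
  eng.rule_lhs = rule_lhs; eng.rule_pt = rule_pt; eng.rule_na = rule_na;
  eng.rule_lp = rule_lp; eng.atom_type = atom_type; eng.atom_ref = atom_ref;
  for (int t = 0; t < pair_mats.size(); ++t)
    eng.pair_sc.push_back(as<NumericMatrix>(pair_mats[t]));
  for (int t = 0; t < hmm_mats.size(); ++t)
    eng.hmm_sc.push_back(as<NumericMatrix>(hmm_mats[t]));

  std::vector<double> V((size_t)n_nt * (L + 1) * (L + 1), NEG_INF);
  eng.V = &V;

  int nrules = rule_lhs.size();
  std::vector<std::vector<int>> rules_of(n_nt);
  for (int k = 0; k < nrules; ++k) rules_of[rule_lhs[k] - 1].push_back(k);

  for (int len = 0; len <= L; ++len) {
    int imax = (len == 0) ? L + 1 : L - len + 1;
    for (int i = 1; i <= imax; ++i) {
      int j = i + len - 1;
      for (int t = 0; t < topo.size(); ++t) {
        int nt = topo[t];
        double acc = NEG_INF;
        for (int k : rules_of[nt - 1]) {
          double body = eng.rule_body(k, i, j);
          if (body == NEG_INF) continue;
          double cand = rule_lp[k] + body;
          if (mode == 0) { if (cand > acc) acc = cand; }
          else acc = lse2(acc, cand);
        }
        V[eng.vidx(nt, i, j)] = acc;
      }
    }
  }
  return NumericVector(V.begin(), V.end());
}
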