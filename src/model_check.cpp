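// Bounded enumeration of linear Kripke models.
//
// A world is a bitmask over the atom alphabet.  A literal is (mask, pos):
// it holds in world w iff (w & mask) != 0 for positive literals and
// (w & mask) == 0 for negative ones (closed world).  Rules arrive encoded
// as [kind, nc, ne, (mask,pos)*nc, (mask,pos)*ne] with kind 0 = normal,
// 1 = persistent, 2 = remnant; the effect set is read distributively (one
// obligation per effect literal, conjunctive cause).
//
// Violations of a rule at world t depend only on worlds 1..t, so a
// depth-first search over world sequences can prune a prefix as soon as
// any rule is violated: no extension can repair it.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

struct Lit {
  uint32_t mask;
  bool pos;
};

struct Rule {
  int kind;
  std::vector<Lit> cause, effect;
};

static inline bool lit_holds(uint32_t w, const Lit &l) {
  return l.pos ? (w & l.mask) != 0u : (w & l.mask) == 0u;
}

static inline bool set_holds(uint32_t w, const std::vector<Lit> &s) {
  for (const Lit &l : s)
    if (!lit_holds(w, l)) return false;
  return true;
}

static std::vector<Rule> parse_rules(const List &rules) {
  std::vector<Rule> out;
  out.reserve(rules.size());
  for (R_xlen_t i = 0; i < rules.size(); ++i) {
    IntegerVector v = rules[i];
    Rule r;
    r.kind = v[0];
    int nc = v[1], ne = v[2], k = 3;
    for (int j = 0; j < nc; ++j, k += 2)
      r.cause.push_back({(uint32_t)v[k], v[k + 1] != 0});
    for (int j = 0; j < ne; ++j, k += 2)
      r.effect.push_back({(uint32_t)v[k], v[k + 1] != 0});
    out.push_back(std::move(r));
  }
  return out;
}

static std::vector<Lit> parse_spots(const List &spots) {
  std::vector<Lit> out;
  for (R_xlen_t i = 0; i < spots.size(); ++i) {
    IntegerVector v = spots[i];
    out.push_back({(uint32_t)v[0], v[1] != 0});
  }
  return out;
}

// is rule r violated at index t (0-based) of the world sequence?
static bool violated_at(const std::vector<uint32_t> &seq, int t,
                        const Rule &r) {
  uint32_t w = seq[t];
  for (const Lit &e : r.effect) {
    if (!lit_holds(w, e)) continue;
    bool cause_earlier = false;
    for (int s = 0; s < t; ++s)
      if (set_holds(seq[s], r.cause)) { cause_earlier = true; break; }
    if (r.kind == 0) {                       // normal
      if (!cause_earlier) return true;
    } else if (r.kind == 1) {                // persistent
      if (!cause_earlier || !set_holds(w, r.cause)) return true;
    } else {                                 // remnant
      if (t == 0) {
        if (!set_holds(w, r.cause)) return true;
      } else if (!lit_holds(seq[t - 1], e) && !cause_earlier) {
        return true;
      }
    }
  }
  return false;
}

static bool spots_met(const std::vector<uint32_t> &seq,
                      const std::vector<Lit> &spots) {
  for (const Lit &sp : spots) {
    bool ok = false;
    for (uint32_t w : seq)
      if (lit_holds(w, sp)) { ok = true; break; }
    if (!ok) return false;
  }
  return true;
}

// candidate world order: empty first, saturated second (these settle the
// common all-negative / all-positive effect shapes immediately)
static std::vector<uint32_t> world_order(int n_atoms) {
  uint32_t full = (n_atoms >= 32) ? 0xffffffffu
                                  : ((1u << n_atoms) - 1u);
  std::vector<uint32_t> ord;
  ord.push_back(0u);
  if (full != 0u) ord.push_back(full);
  for (uint32_t w = 1; w < full; ++w) ord.push_back(w);
  return ord;
}

// [[Rcpp::export]]
List cpp_check_model(IntegerVector worlds, List rules, List spots) {
  std::vector<uint32_t> seq(worlds.begin(), worlds.end());
  std::vector<Rule> rs = parse_rules(rules);
  std::vector<Lit> sp = parse_spots(spots);
  LogicalVector rule_ok(rs.size()), spot_ok(sp.size());
  for (size_t i = 0; i < rs.size(); ++i) {
    bool ok = true;
    for (int t = 0; t < (int)seq.size(); ++t)
      if (violated_at(seq, t, rs[i])) { ok = false; break; }
    rule_ok[i] = ok;
  }
  for (size_t i = 0; i < sp.size(); ++i) {
    bool ok = false;
    for (uint32_t w : seq)
      if (lit_holds(w, sp[i])) { ok = true; break; }
    spot_ok[i] = ok;
  }
  return List::create(_["rule_ok"] = rule_ok, _["spot_ok"] = spot_ok);
}

// status: 0 = exhausted without witness, 1 = witness found, 2 = node limit
// [[Rcpp::export]]
List cpp_exists_model(int n_atoms, int bound, List rules, List spots,
                      double max_nodes) {
  std::vector<Rule> rs = parse_rules(rules);
  std::vector<Lit> sp = parse_spots(spots);
  std::vector<uint32_t> ord = world_order(n_atoms);
  const size_t nw = ord.size();
  std::vector<uint32_t> seq;
  std::vector<size_t> idx;  // idx[d]: next candidate index at depth d
  double nodes = 0.0;
  seq.reserve(bound);
  idx.push_back(0);
  while (!idx.empty()) {
    int d = (int)idx.size() - 1;
    if (idx[d] >= nw) {          // exhausted this depth
      idx.pop_back();
      if (!seq.empty()) seq.pop_back();
      if (!idx.empty()) ++idx.back();
      continue;
    }
    uint32_t w = ord[idx[d]];
    if ((double)(++nodes) > max_nodes)
      return List::create(_["status"] = 2, _["worlds"] = R_NilValue,
                          _["nodes"] = nodes);
    seq.push_back(w);
    bool viol = false;
    for (const Rule &r : rs)
      if (violated_at(seq, d, r)) { viol = true; break; }
    if (!viol && spots_met(seq, sp))
      return List::create(_["status"] = 1,
                          _["worlds"] = IntegerVector(seq.begin(), seq.end()),
                          _["nodes"] = nodes);
    if (!viol && (int)seq.size() < bound) {
      idx.push_back(0);          // descend
    } else {
      seq.pop_back();
      ++idx[d];                  // next sibling
    }
  }
  return List::create(_["status"] = 0, _["worlds"] = R_NilValue,
                      _["nodes"] = nodes);
}

// Search for a model satisfying q but violating p (a counterexample to
// behavioural inclusion).  status: 0 = none (inclusion holds up to the
// bound), 1 = counterexample found, 2 = node limit.
// [[Rcpp::export]]
List cpp_includes(int n_atoms, int bound, List q_rules, List q_spots,
                  List p_rules, List p_spots, double max_nodes) {
  std::vector<Rule> qr = parse_rules(q_rules);
  std::vector<Lit> qs = parse_spots(q_spots);
  std::vector<Rule> pr = parse_rules(p_rules);
  std::vector<Lit> ps = parse_spots(p_spots);
  std::vector<uint32_t> ord = world_order(n_atoms);
  const size_t nw = ord.size();
  std::vector<uint32_t> seq;
  std::vector<size_t> idx;
  std::vector<char> pviol;       // p-rule violation flag per depth
  double nodes = 0.0;
  idx.push_back(0);
  while (!idx.empty()) {
    int d = (int)idx.size() - 1;
    if (idx[d] >= nw) {
      idx.pop_back();
      if (!seq.empty()) { seq.pop_back(); pviol.pop_back(); }
      if (!idx.empty()) ++idx.back();
      continue;
    }
    uint32_t w = ord[idx[d]];
    if ((double)(++nodes) > max_nodes)
      return List::create(_["status"] = 2, _["worlds"] = R_NilValue,
                          _["nodes"] = nodes);
    seq.push_back(w);
    bool qviol = false;
    for (const Rule &r : qr)
      if (violated_at(seq, d, r)) { qviol = true; break; }
    if (qviol) {                 // no q-model extends this prefix
      seq.pop_back();
      ++idx[d];
      continue;
    }
    bool pv = (d > 0 && pviol[d - 1]);
    if (!pv)
      for (const Rule &r : pr)
        if (violated_at(seq, d, r)) { pv = true; break; }
    pviol.push_back(pv ? 1 : 0);
    if (spots_met(seq, qs) && (pv || !spots_met(seq, ps)))
      return List::create(_["status"] = 1,
                          _["worlds"] = IntegerVector(seq.begin(), seq.end()),
                          _["nodes"] = nodes);
    if ((int)seq.size() < bound) {
      idx.push_back(0);
    } else {
      seq.pop_back();
      pviol.pop_back();
      ++idx[d];
    }
  }
  return List::create(_["status"] = 0, _["worlds"] = R_NilValue,
                      _["nodes"] = nodes);
}
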