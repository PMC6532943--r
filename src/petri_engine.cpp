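#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Fast batch simulator for 4-node regulatory Petri nets.
//
// Semantics (mirrored by the pure-R reference in R/petri_sim.R):
//  * nodes R1, R2, G1, G2 (places 0..3); edge matrix row-major, m[src*4+tgt],
//    entries are resolved signed weights (0, +-1, +-W)
//  * regulators are provisioned 200 tokens unless an edge from the other
//    regulator exists (of either sign); all other places start empty
//  * activating edge X -> Y (weight w): transition consuming 1 token from X,
//    delivering w tokens to Y; two same-magnitude activators combine as a
//    single AND transition (consume 1 from each, deliver w) or as two OR
//    transitions, per the model's logic variant
//  * a node with inhibitor-only input gets a constitutive source transition
//    delivering `src_rate` tokens per step
//  * inhibition dominates: all transitions producing into a node are disabled
//    while an inhibitor of that node holds >= 1 token (AND variant of a
//    double-inhibitor node: only while both inhibitors hold tokens)
//  * deletion: the place starts empty and every output effect into it is
//    removed; transitions themselves persist and still consume
//  * synchronous maximal-parallel firing, enablement on the pre-step marking;
//    when consumption demand exceeds a place's tokens, enabled transitions
//    are funded greedily in rng-shuffled order (sole source of randomness)

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Trans {
  int nIn;        // consumed input places (1 token each)
  int in[2];
  int out;        // output place
  int delta;      // token delta (+w activation, +src_rate source; 0 if deleted)
  int nGate;      // inhibitor gate places
  int gate[2];
  bool gateAll;   // true: disabled only when ALL gates hold tokens
};

struct Net {
  Trans tr[12];
  int nt;
  int init[4];
};

static void compile_net(const int *m, const int *andf, const bool *del,
                        int tokens, int src_rate, Net &net) {
  net.nt = 0;
  for (int j = 0; j < 4; ++j) net.init[j] = 0;
  for (int j = 0; j < 2; ++j) {
    if (del[j]) continue;
    if (m[(1 - j) * 4 + j] == 0) net.init[j] = tokens;
  }
  for (int j = 0; j < 4; ++j) {
    int acts[2], actw[2], na = 0, inhs[2], ni = 0;
    for (int s = 0; s < 4; ++s) {
      int w = m[s * 4 + j];
      if (s == j || w == 0) continue;
      if (w > 0) { acts[na] = s; actw[na] = w; ++na; }
      else inhs[ni++] = s;
    }
    bool isAnd = andf[j] != 0;
    int mult = del[j] ? 0 : 1;
    int first = net.nt;
    if (na == 2 && isAnd) {
      Trans &t = net.tr[net.nt++];
      t.nIn = 2; t.in[0] = acts[0]; t.in[1] = acts[1];
      t.out = j; t.delta = actw[0] * mult; t.nGate = 0; t.gateAll = false;
    } else {
      for (int a = 0; a < na; ++a) {
        Trans &t = net.tr[net.nt++];
        t.nIn = 1; t.in[0] = acts[a];
        t.out = j; t.delta = actw[a] * mult; t.nGate = 0; t.gateAll = false;
      }
    }
    if (na == 0 && ni >= 1) {
      Trans &t = net.tr[net.nt++];
      t.nIn = 0; t.out = j; t.delta = src_rate * mult;
      t.nGate = 0; t.gateAll = false;
    }
    // inhibition gates every producer of node j
    if (ni > 0) {
      for (int t = first; t < net.nt; ++t) {
        net.tr[t].nGate = ni;
        for (int i = 0; i < ni; ++i) net.tr[t].gate[i] = inhs[i];
        net.tr[t].gateAll = (isAnd && ni == 2);
      }
    }
  }
}

static void run_net(const Net &net, int nSteps, uint64_t rngState, int *outG) {
  int tok[4];
  for (int j = 0; j < 4; ++j) tok[j] = net.init[j];
  int enabled[12], ord[12];
  for (int step = 0; step < nSteps; ++step) {
    int ne = 0, demand[4] = {0, 0, 0, 0};
    for (int t = 0; t < net.nt; ++t) {
      const Trans &tr = net.tr[t];
      bool ok = true;
      for (int i = 0; i < tr.nIn; ++i)
        if (tok[tr.in[i]] < 1) { ok = false; break; }
      if (ok && tr.nGate > 0) {
        if (tr.gateAll) {
          bool all = true;
          for (int g = 0; g < tr.nGate; ++g)
            if (tok[tr.gate[g]] < 1) { all = false; break; }
          if (all) ok = false;
        } else {
          for (int g = 0; g < tr.nGate; ++g)
            if (tok[tr.gate[g]] >= 1) { ok = false; break; }
        }
      }
      if (ok) {
        enabled[ne++] = t;
        for (int i = 0; i < tr.nIn; ++i) demand[tr.in[i]]++;
      }
    }
    bool conflict = false;
    for (int j = 0; j < 4; ++j)
      if (demand[j] > tok[j]) { conflict = true; break; }
    long prod[4] = {0, 0, 0, 0};
    if (!conflict) {
      for (int k = 0; k < ne; ++k) {
        const Trans &tr = net.tr[enabled[k]];
        for (int i = 0; i < tr.nIn; ++i) tok[tr.in[i]]--;
        prod[tr.out] += tr.delta;
      }
    } else {
      for (int k = 0; k < ne; ++k) ord[k] = enabled[k];
      for (int k = ne - 1; k > 0; --k) {  // Fisher-Yates
        int r = (int)(splitmix64(rngState) % (uint64_t)(k + 1));
        int tmp = ord[k]; ord[k] = ord[r]; ord[r] = tmp;
      }
      for (int k = 0; k < ne; ++k) {
        const Trans &tr = net.tr[ord[k]];
        bool funded = true;
        for (int i = 0; i < tr.nIn; ++i)
          if (tok[tr.in[i]] < 1) { funded = false; break; }
        if (!funded) continue;
        for (int i = 0; i < tr.nIn; ++i) tok[tr.in[i]]--;
        prod[tr.out] += tr.delta;
      }
    }
    for (int j = 0; j < 4; ++j) {
      long v = (long)tok[j] + prod[j];
      tok[j] = v < 0 ? 0 : (v > 1000000000L ? 1000000000 : (int)v);
    }
  }
  outG[0] = tok[2];
  outG[1] = tok[3];
}

//' @title Batch Petri net simulation (compiled core)
//' @description Internal engine behind [simulate_models()]. Runs every model
//'   under the four deletion conditions (wild type, R1, R2, R1+R2) for the
//'   requested number of stochastic repeats.
//' @param mats integer matrix, one model per row, 16 row-major entries with
//'   resolved signed weights.
//' @param and_flags integer matrix (models x 4), 1 where the node uses the
//'   AND input logic.
//' @param steps,runs,tokens,src_rate scalar simulation settings.
//' @param seeds numeric vector of per-model rng seeds.
//' @return numeric vector of final G1/G2 token counts, laid out as
//'   models x runs x conditions(WT, R1d, R2d, R1dR2d) x genes(G1, G2) with
//'   gene fastest.
//' @keywords internal
// [[Rcpp::export(name = ".engine_simulate")]]
NumericVector engine_simulate(IntegerMatrix mats, IntegerMatrix and_flags,
                              int steps, int runs, int tokens, int src_rate,
                              NumericVector seeds) {
  int N = mats.nrow();
  if (and_flags.nrow() != N || seeds.size() != N)
    stop("mats, and_flags and seeds must agree on the number of models");
  NumericVector out((size_t)N * runs * 4 * 2);
  std::vector<int> mrow(16), arow(4);
  for (int n = 0; n < N; ++n) {
    for (int k = 0; k < 16; ++k) mrow[k] = mats(n, k);
    for (int k = 0; k < 4; ++k) arow[k] = and_flags(n, k);
    for (int cond = 0; cond < 4; ++cond) {
      bool del[4] = {cond == 1 || cond == 3, cond == 2 || cond == 3,
                     false, false};
      Net net;
      compile_net(mrow.data(), arow.data(), del, tokens, src_rate, net);
      for (int r = 0; r < runs; ++r) {
        uint64_t s = (uint64_t)(int64_t)seeds[n];
        uint64_t state = s * 0x100000001b3ULL + (uint64_t)(r * 4 + cond + 1);
        int g[2];
        run_net(net, steps, state, g);
        out[(((size_t)n * runs + r) * 4 + cond) * 2 + 0] = g[0];
        out[(((size_t)n * runs + r) * 4 + cond) * 2 + 1] = g[1];
      }
    }
  }
  return out;
}
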