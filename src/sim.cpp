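#include <Rcpp.h>
using namespace Rcpp;

// Stochastic Boolean update kernel for a phosphorylation lattice.
//
// Node encoding (all vectors length n, indices 1-based, 0 = absent slot):
//   species: 0 = RsbR, 1 = RsbS
//   cls:     1 = R1, 2 = R2, 3 = R3, 4 = S1
//   sol:     index of the solitary (unpaired-species) neighbour
//   p1, p2:  indices of the same-species neighbour pair
// An absent neighbour slot contributes a fixed 0 bit (used by toy fixtures;
// the canonical 60-node lattice has all slots filled).
//
// pa is a 4 x 6 matrix of allosteric parameters, rows R1, R2, R3, S1.
// For R1/R2/S1 the column key is sol_bit * 3 + (pair bit sum) in 0..5;
// for R3 all three neighbour bits are pooled and the key is their sum 0..3.
//
// kphr_t gives the RsbR maximum phosphorylation probability at every step
// (the stress schedule, already expanded); its length sets the step count.
// Updates are sequential in a fresh uniform random permutation per step
// (later nodes see earlier flips) unless synchronous = true, in which case
// all decisions read the state frozen at the start of the step.
//
// Uses R's RNG stream, so results are reproducible under set.seed().

static inline int nb_bit(const std::vector<int>& st, int idx) {
  return idx > 0 ? st[idx - 1] : 0;
}

// [[Rcpp::export]]
List sim_run_cpp(IntegerVector species, IntegerVector cls,
                 IntegerVector sol, IntegerVector p1, IntegerVector p2,
                 NumericMatrix pa, NumericVector kphr_t,
                 double kphs, double kdpr, double kdps,
                 IntegerVector init, bool synchronous, bool record_bits) {
  const int n = species.size();
  const int n_steps = kphr_t.size();

  std::vector<int> st(n), frozen(n);
  int nR = 0, nS = 0;
  for (int i = 0; i < n; ++i) {
    st[i] = init[i];
    if (species[i] == 0) ++nR; else ++nS;
  }

  NumericMatrix frac(n_steps + 1, 2);
  IntegerMatrix bits;
  if (record_bits) bits = IntegerMatrix(n_steps + 1, n);

  std::vector<int> perm(n);

  for (int t = 0; t <= n_steps; ++t) {
    if (t > 0) {
      const double kphr = kphr_t[t - 1];
      // Fisher-Yates permutation from R's uniform stream
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
      if (synchronous) frozen = st;
      const std::vector<int>& rd = synchronous ? frozen : st;

      for (int k = 0; k < n; ++k) {
        const int i = perm[k];
        double p;
        if (st[i] == 0) {
          double pav;
          if (cls[i] == 3) {
            int s = nb_bit(rd, sol[i]) + nb_bit(rd, p1[i]) + nb_bit(rd, p2[i]);
            pav = pa(2, s);
          } else {
            int key = nb_bit(rd, sol[i]) * 3 +
                      nb_bit(rd, p1[i]) + nb_bit(rd, p2[i]);
            pav = pa(cls[i] - 1, key);
          }
          p = pav * (species[i] == 0 ? kphr : kphs);
          if (unif_rand() < p) st[i] = 1;
        } else {
          p = (species[i] == 0) ? kdpr : kdps;
          if (unif_rand() < p) st[i] = 0;
        }
      }
    }
    int sR = 0, sS = 0;
    for (int i = 0; i < n; ++i) {
      if (species[i] == 0) sR += st[i]; else sS += st[i];
    }
    frac(t, 0) = nR > 0 ? (double)sR / nR : NA_REAL;
    frac(t, 1) = nS > 0 ? (double)sS / nS : NA_REAL;
    if (record_bits) for (int i = 0; i < n; ++i) bits(t, i) = st[i];
  }

  IntegerVector final_state(n);
  for (int i = 0; i < n; ++i) final_state[i] = st[i];

  List out = List::create(_["frac"] = frac, _["final"] = final_state);
  if (record_bits) out["bits"] = bits;
  return out;
}
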