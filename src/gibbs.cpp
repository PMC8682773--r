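#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Single-site heat-bath Gibbs sampler for a pairwise Potts model over q
// states (the gap is the last state). Fields h are L x q, edges an E x 2
// matrix of 1-based site pairs (i < j), couplings a list of q x q blocks
// on the log scale. Uses R's RNG, so set.seed() in R controls the draw.
// With allowGap = false the last state is excluded from every conditional
// (used to draw gap-free target sequences from the same model).
// [[Rcpp::export]]
IntegerMatrix gibbsSamplePotts(int L, int q, NumericMatrix h,
                               IntegerMatrix edges, List couplings,
                               int M, int burninSweeps, int thinSweeps,
                               bool allowGap) {
  int E = edges.nrow();
  std::vector<std::vector<int> > nbr(L), eidx(L), isFirst(L);
  for (int e = 0; e < E; ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    nbr[i].push_back(j); eidx[i].push_back(e); isFirst[i].push_back(1);
    nbr[j].push_back(i); eidx[j].push_back(e); isFirst[j].push_back(0);
  }
  std::vector<NumericMatrix> J;
  J.reserve(E);
  for (int e = 0; e < E; ++e) J.push_back(as<NumericMatrix>(couplings[e]));

  int qEff = allowGap ? q : q - 1;
  std::vector<int> s(L);
  for (int i = 0; i < L; ++i) {
    s[i] = (int)(unif_rand() * qEff);
    if (s[i] >= qEff) s[i] = qEff - 1;
  }
  IntegerMatrix out(M, L);
  std::vector<double> w(q);
  long totalSweeps = (long)burninSweeps + (long)M * thinSweeps;
  int taken = 0;
  for (long sweep = 1; sweep <= totalSweeps && taken < M; ++sweep) {
    for (int i = 0; i < L; ++i) {
      double mx = R_NegInf;
      for (int a = 0; a < qEff; ++a) {
        double lp = h(i, a);
        for (size_t t = 0; t < nbr[i].size(); ++t) {
          const NumericMatrix& Je = J[eidx[i][t]];
          int b = s[nbr[i][t]];
          lp += isFirst[i][t] ? Je(a, b) : Je(b, a);
        }
        w[a] = lp;
        if (lp > mx) mx = lp;
      }
      double tot = 0.0;
      for (int a = 0; a < qEff; ++a) {
        w[a] = std::exp(w[a] - mx);
        tot += w[a];
      }
      double u = unif_rand() * tot, c = 0.0;
      int pick = qEff - 1;
      for (int a = 0; a < qEff; ++a) {
        c += w[a];
        if (u <= c) { pick = a; break; }
      }
      s[i] = pick;
    }
    if (sweep > burninSweeps && (sweep - burninSweeps) % thinSweeps == 0) {
      for (int i = 0; i < L; ++i) out(taken, i) = s[i] + 1;
      ++taken;
    }
  }
  return out;
}
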