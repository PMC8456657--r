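#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Forward-in-time Wright-Fisher simulation of one genomic segment in an
// admixed population, with additive selection at a focal SNP.
//
// alleles, anc: 2N x S integer matrices of founder haplotypes (0/1 alleles,
// 0/1 ancestry labels with 1 = P). Haplotypes 2j, 2j+1 form diploid j.
// Each generation, every offspring haplotype is a recombinant gamete of one
// parent diploid chosen with probability proportional to its fitness at the
// focal SNP: 1, 1-s, 1-2s for 2, 1, 0 copies of the favoured allele
// (clamped at 0). Crossover count per gamete is Poisson(rec * span_bp) with
// uniform crossover positions, a uniform genetic map over the segment.
//
// Returns the final-generation haplotype alleles and ancestry labels.
// [[Rcpp::export]]
List forward_selection_cpp(IntegerMatrix alleles, IntegerMatrix anc,
                           NumericVector pos, double rec, int gens,
                           int focal, int favored, double s) {
  const int H = alleles.nrow(); // 2N haplotypes
  const int S = alleles.ncol();
  if (H % 2 != 0) stop("forward_selection_cpp: odd haplotype count");
  if (anc.nrow() != H || anc.ncol() != S)
    stop("forward_selection_cpp: ancestry matrix shape mismatch");
  if (focal < 0 || focal >= S) stop("forward_selection_cpp: focal out of range");
  const int N = H / 2;
  const double span = pos[S - 1] - pos[0];
  const double xlen = rec * (span > 0 ? span : 0); // expected crossovers

  // double buffers
  std::vector<int> curA(H * S), curC(H * S), nxtA(H * S), nxtC(H * S);
  for (int h = 0; h < H; ++h)
    for (int t = 0; t < S; ++t) {
      curA[h * S + t] = alleles(h, t);
      curC[h * S + t] = anc(h, t);
    }

  std::vector<double> cumw(N);
  std::vector<double> cross;
  for (int gen = 0; gen < gens; ++gen) {
    // diploid fitness at the focal SNP
    double tot = 0.0;
    for (int j = 0; j < N; ++j) {
      int cnt = (curA[(2 * j) * S + focal] == favored) +
                (curA[(2 * j + 1) * S + focal] == favored);
      double w = 1.0 - s * (2 - cnt);
      if (w < 0) w = 0;
      tot += w;
      cumw[j] = tot;
    }
    if (!(tot > 0)) stop("forward_selection_cpp: population fitness is zero");

    for (int h = 0; h < H; ++h) {
      // parent diploid by inverse-CDF on cumulative fitness
      double u = R::unif_rand() * tot;
      int j = std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin();
      if (j >= N) j = N - 1;
      const int p0 = 2 * j, p1 = 2 * j + 1;
      int ncross = (xlen > 0) ? (int)R::rpois(xlen) : 0;
      int from = (R::unif_rand() < 0.5) ? p0 : p1;
      if (ncross == 0) {
        std::copy(&curA[from * S], &curA[from * S] + S, &nxtA[h * S]);
        std::copy(&curC[from * S], &curC[from * S] + S, &nxtC[h * S]);
      } else {
        cross.resize(ncross);
        for (int k = 0; k < ncross; ++k)
          cross[k] = pos[0] + R::unif_rand() * span;
        std::sort(cross.begin(), cross.end());
        int k = 0;
        int src = from;
        for (int t = 0; t < S; ++t) {
          while (k < ncross && cross[k] <= pos[t]) {
            src = (src == p0) ? p1 : p0;
            ++k;
          }
          nxtA[h * S + t] = curA[src * S + t];
          nxtC[h * S + t] = curC[src * S + t];
        }
      }
    }
    std::swap(curA, nxtA);
    std::swap(curC, nxtC);
  }

  IntegerMatrix outA(H, S), outC(H, S);
  for (int h = 0; h < H; ++h)
    for (int t = 0; t < S; ++t) {
      outA(h, t) = curA[h * S + t];
      outC(h, t) = curC[h * S + t];
    }
  return List::create(_["alleles"] = outA, _["ancestry"] = outC);
}
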