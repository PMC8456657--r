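#include <Rcpp.h>
using namespace Rcpp;

// Diploid local-ancestry HMM over unphased genotypes.
//
// Hidden state q in {0,1,2} = copies of P ancestry carried by an individual
// at a marker. Each haplotype follows an independent two-state Markov chain:
// over genetic distance d Morgans the chain switches with probability
// 1 - exp(-g*d) into the stationary distribution (m, 1-m). The diploid
// transition kernel is the product of the two haplotype chains collapsed to
// copy counts (for q = 1 the P-carrying and A-carrying haplotypes are
// distinguishable, so the collapse is exact, not binomial).
//
// Emission: given its ancestry, a haplotype carries the alternate allele with
// error-adjusted panel frequency f' = (1-eps)f + eps(1-f); the genotype
// likelihood is the convolution over the two haplotypes. Missing genotypes
// (NA) emit likelihood 1.
//
// The forward variables are rescaled at every site (no unscaled products);
// posteriors are checked to sum to one within 1e-10 before use.
//
// geno: snps x individuals, values 0/1/2 or NA. chrom_id: integer id per SNP;
// a change of id restarts the chain at the stationary diploid distribution.
// [[Rcpp::export]]
List hmm_dosage_cpp(IntegerMatrix geno, NumericVector fP, NumericVector fA,
                    NumericVector pos, IntegerVector chrom_id,
                    double g, double m, double rec, double eps) {
  const int S = geno.nrow();
  const int n_ind = geno.ncol();
  if (fP.size() != S || fA.size() != S || pos.size() != S || chrom_id.size() != S)
    stop("hmm_dosage_cpp: input length mismatch");

  // per-SNP emission table e[state][genotype]
  std::vector<double> emit(S * 9);
  for (int t = 0; t < S; ++t) {
    double p1 = (1.0 - eps) * fP[t] + eps * (1.0 - fP[t]);
    double a1 = (1.0 - eps) * fA[t] + eps * (1.0 - fA[t]);
    double *e = &emit[t * 9];
    // state 0: both haplotypes A
    e[0 * 3 + 0] = (1 - a1) * (1 - a1);
    e[0 * 3 + 1] = 2 * a1 * (1 - a1);
    e[0 * 3 + 2] = a1 * a1;
    // state 1: one P, one A haplotype
    e[1 * 3 + 0] = (1 - p1) * (1 - a1);
    e[1 * 3 + 1] = p1 * (1 - a1) + (1 - p1) * a1;
    e[1 * 3 + 2] = p1 * a1;
    // state 2: both P
    e[2 * 3 + 0] = (1 - p1) * (1 - p1);
    e[2 * 3 + 1] = 2 * p1 * (1 - p1);
    e[2 * 3 + 2] = p1 * p1;
  }

  // per-interval diploid transition matrices (shared by all individuals)
  std::vector<double> trans(S * 9); // trans for step t-1 -> t stored at t
  std::vector<bool> restart(S);
  restart[0] = true;
  const double init[3] = {(1 - m) * (1 - m), 2 * m * (1 - m), m * m};
  for (int t = 1; t < S; ++t) {
    if (chrom_id[t] != chrom_id[t - 1]) {
      restart[t] = true;
      continue;
    }
    restart[t] = false;
    double d = (pos[t] - pos[t - 1]) * rec; // Morgans, uniform map
    if (d < 0) stop("hmm_dosage_cpp: positions not sorted at SNP %d", t + 1);
    double r = 1.0 - std::exp(-g * d);
    double pPP = (1 - r) + r * m, pPA = r * (1 - m);
    double pAP = r * m, pAA = (1 - r) + r * (1 - m);
    double *T = &trans[t * 9]; // T[q*3 + q']
    T[0 * 3 + 0] = pAA * pAA;
    T[0 * 3 + 1] = 2 * pAA * pAP;
    T[0 * 3 + 2] = pAP * pAP;
    T[1 * 3 + 0] = pPA * pAA;
    T[1 * 3 + 1] = pPP * pAA + pPA * pAP;
    T[1 * 3 + 2] = pPP * pAP;
    T[2 * 3 + 0] = pPA * pPA;
    T[2 * 3 + 1] = 2 * pPP * pPA;
    T[2 * 3 + 2] = pPP * pPP;
  }

  NumericMatrix dosage(S, n_ind);
  std::vector<double> alpha(S * 3), beta(S * 3), scale(S);
  double loglik = 0.0, max_dev = 0.0;

  for (int ind = 0; ind < n_ind; ++ind) {
    // forward with per-site scaling
    for (int t = 0; t < S; ++t) {
      int gt = geno(t, ind);
      const double *e = &emit[t * 9];
      double a0, a1, a2;
      if (restart[t]) {
        a0 = init[0]; a1 = init[1]; a2 = init[2];
      } else {
        const double *T = &trans[t * 9];
        const double *ap = &alpha[(t - 1) * 3];
        a0 = ap[0] * T[0] + ap[1] * T[3] + ap[2] * T[6];
        a1 = ap[0] * T[1] + ap[1] * T[4] + ap[2] * T[7];
        a2 = ap[0] * T[2] + ap[1] * T[5] + ap[2] * T[8];
      }
      if (gt != NA_INTEGER) {
        a0 *= e[0 * 3 + gt]; a1 *= e[1 * 3 + gt]; a2 *= e[2 * 3 + gt];
      }
      double c = a0 + a1 + a2;
      if (!(c > 0.0) || !R_finite(c))
        stop("hmm_dosage_cpp: non-finite likelihood at SNP %d (individual %d)",
             t + 1, ind + 1);
      alpha[t * 3 + 0] = a0 / c;
      alpha[t * 3 + 1] = a1 / c;
      alpha[t * 3 + 2] = a2 / c;
      scale[t] = c;
      loglik += std::log(c);
    }
    // backward, sharing the forward scale factors
    beta[(S - 1) * 3 + 0] = beta[(S - 1) * 3 + 1] = beta[(S - 1) * 3 + 2] = 1.0;
    for (int t = S - 2; t >= 0; --t) {
      double b0, b1, b2;
      if (restart[t + 1]) {
        b0 = b1 = b2 = 1.0; // next chromosome contributes a constant factor
      } else {
        const double *T = &trans[(t + 1) * 9];
        const double *e = &emit[(t + 1) * 9];
        int gt = geno(t + 1, ind);
        double eb0 = 1.0, eb1 = 1.0, eb2 = 1.0;
        if (gt != NA_INTEGER) {
          eb0 = e[0 * 3 + gt]; eb1 = e[1 * 3 + gt]; eb2 = e[2 * 3 + gt];
        }
        const double *bn = &beta[(t + 1) * 3];
        b0 = T[0] * eb0 * bn[0] + T[1] * eb1 * bn[1] + T[2] * eb2 * bn[2];
        b1 = T[3] * eb0 * bn[0] + T[4] * eb1 * bn[1] + T[5] * eb2 * bn[2];
        b2 = T[6] * eb0 * bn[0] + T[7] * eb1 * bn[1] + T[8] * eb2 * bn[2];
        double c = scale[t + 1];
        b0 /= c; b1 /= c; b2 /= c;
      }
      beta[t * 3 + 0] = b0; beta[t * 3 + 1] = b1; beta[t * 3 + 2] = b2;
    }
    // posterior and expected dosage
    for (int t = 0; t < S; ++t) {
      double g0 = alpha[t * 3 + 0] * beta[t * 3 + 0];
      double g1 = alpha[t * 3 + 1] * beta[t * 3 + 1];
      double g2 = alpha[t * 3 + 2] * beta[t * 3 + 2];
      double tot = g0 + g1 + g2;
      double dev = std::fabs(tot - 1.0);
      if (dev > max_dev) max_dev = dev;
      if (dev > 1e-10)
        stop("hmm_dosage_cpp: posterior does not sum to 1 at SNP %d", t + 1);
      dosage(t, ind) = (g1 + 2.0 * g2) / tot;
    }
  }

  return List::create(_["dosage"] = dosage, _["loglik"] = loglik,
                      _["max_posterior_dev"] = max_dev);
}
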