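---
title: "Detecting admixture-enabled selection: models and design choices"
author: "admixsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting admixture-enabled selection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(admixsel)
```

## The problem

A population formed by admixture between two diverged source populations
carries, at every locus, chromosome segments of either source ancestry. Under
neutrality the expected proportion of ancestry from one source is the same
across the genome (the admixture fraction), so a locus where one ancestry is
strongly over-represented is a candidate for post-admixture positive
selection on a variant contributed by that source — *admixture-enabled
selection*. The motivating setting is a Polynesian-type history: an
Asian-related population (source **A**) admixed with a Papuan-related
population (source **P**) roughly 100 generations ago, with ~24.6% of the
admixed genome deriving from P.

`admixsel` implements the full analysis chain:

1. a synthetic-data generator for the two-source demography with true local
   ancestry recorded (`simulate_neutral()`, `ascertain_snps()`,
   `inject_selected_locus()`),
2. local-ancestry dosage inference from unphased genotypes
   (`infer_dosage()`),
3. an ancestry-excess scan with simulation-based error calibration
   (`scan_stats()`, `call_regions()`, `estimate_fwer()`, `fdr_from_fwer()`),
4. f3 / f4-ratio admixture statistics with block-jackknife errors,
5. rejection ABC for a selection coefficient under a Wright–Fisher forward
   model (`abc_estimate()`),
6. two-locus LD from unphased genotypes via EM (`em_haplotypes()`).

## The stated demographic world

All defaults of `demography_config()` encode one fixed scenario, used both as
the null model of the scan and as the test bed of every stochastic check:

| parameter | default | meaning |
|---|---|---|
| `N` | 1000 | diploid size of every population |
| `t_split` | 1667 | generations since P/A divergence (~50 kya at 30 y) |
| `g` | 100 | generations since the single admixture pulse (~3 kya) |
| `alpha_P` | 0.246 | P-ancestry fraction of the admixed population |
| `mu` | 1.2e-8 | mutation rate / bp / generation |
| `rec` | 1.3e-8 | recombination rate / bp / generation |
| `n_segments` | 3000 | independent 1 Mb segments (a 3 Gb genome) |
| samples | 48 / 46 / 90 | chromosomes drawn from P / admixed / A |

The ancestral population before the split (and the internal branch when an
outgroup is added) also has size N — the minimal-parameter choice, flagged in
the simulation provenance since nothing in the target setting pins it down.
Divergence of 1667 generations at N = 1000 corresponds to a fixation index
around 1 − exp(−t/2N) ≈ 0.57: the sources are far more diverged per site than
real human populations, which is what makes a 3 Gb genome's worth of signal
reproducible from a toy population size.

### What the generator does (and does not) emulate

The generator is *frequency-based*. Per segment, candidate-site frequencies
in the common ancestor are drawn from the neutral site-frequency spectrum
(density ∝ 1/x, truncated at the single-copy frequency 1/2N); each branch is
then evolved by per-generation Wright–Fisher binomial sampling of 2N allele
copies (compiled code, with early exit at absorption; interior frequencies
with np(1−p) > 30 use the standard continuity-corrected normal approximation
to the binomial, while draws near the boundaries stay exact so absorption
dynamics are untouched); samples are drawn as Hardy–Weinberg genotypes from
the final frequencies. Admixed haplotypes are ancestry-tract mosaics: tracts
follow the standard pulse-admixture Markov approximation (switch
opportunities Poisson with rate g per Morgan, stationary distribution
(alpha_P, 1 − alpha_P)), and alleles are drawn from the *admixture-time*
source frequencies conditional on local ancestry. The candidate-site
intensity per segment is the pooled-sample Watterson expectation with a
1.6x margin, because drift over 1667 generations fixes a large share of
the (mostly rare) SFS draws before sampling; the ascertainment step then
controls the final SNP count.

Features deliberately *not* reproduced, and their consequences:

* **No within-population LD.** Haplotypes are exchangeable given ancestry and
  frequency. The HMM below does not model background LD either, so inference
  is well-specified; methods that exploit source haplotype structure (e.g.
  ELAI's two-layer cluster model) would gain nothing here. A green accuracy
  test therefore validates the dosage estimand, not robustness to background
  LD.
* **No post-admixture drift of ancestry frequencies.** Each sampled haplotype
  draws its tracts independently, so the per-SNP ancestry proportion has
  binomial sampling variance only (SD ≈ 6–7 percentage points across SNPs at
  46 haplotypes) and lacks the extra locus-level drift component a full
  forward model would add (~3 points at these parameters, in quadrature).
  Scan thresholds are computed per run from that run's own mean and SD, so
  the scan calibration is internally consistent; absolute SDs are modestly
  understated relative to a full coalescent.
* **No new mutations after the split.** Population-private young variants are
  under-represented; ascertainment (below) restores the intended MAF profile.
* **Mildly shrunken f4-ratio estimand.** Because admixed lineages leave the A
  branch g generations before the present, the f4-ratio estimates
  alpha_A × F(t_split − g)/F(t_split) with F(t) = 1 − exp(−t/2N) — a ≈ 4%
  shrinkage at N = 1000 that vanishes at human-scale N_e. Recovery tests
  target the drift-adjusted expectation.

Segments are genetically independent. They are laid out on pseudo-chromosomes
of 150 segments with a 5 Mb stride, so the inter-segment genetic distance
(g·rec·4 Mb ≈ 5.2) makes the ancestry chain effectively stationary across
segments and the region-merge rule (< 1 Mb) can never join runs across
segments — "free recombination between segments" in a single coordinate
system.

### Ascertainment

Array data over-represent common variants. `ascertain_snps()` bins SNPs by
pooled-sample minor-allele frequency into equal-width bins over (0, 0.5]
(width 0.05 by default; the paper-scale target count 162,358 is scaled by
`n_segments`/3000), computes per-bin quotas from a reference histogram by
largest-remainder rounding, and samples at random within bins. The default
reference histogram is uniform across bins — a coarse description of a
genotyping array's flat MAF spectrum; when a bin cannot fill its quota all
its SNPs are kept and a warning is logged (quotas are not redistributed).

### The selected-locus fixture

`inject_selected_locus()` re-simulates one segment of the admixed population
forward in time: 2N founder haplotypes drawn from the admixture pulse, g
generations of random mating with Poisson recombination, and additive
selection (genotype fitnesses 1, 1 − s, 1 − 2s) at a focal SNP. The focal
SNP is the most P-diagnostic SNP within 250 kb of the requested position, so
the favoured allele is a P-derived variant whose initial frequency follows
the admixture convention p0 = f_P·alpha_P + f_A·(1 − alpha_P) by
construction. Because recombination acts on real haplotypes, P ancestry
linked to the selected allele hitch-hikes upward, which is the signal the
scan is designed to detect.

## Local ancestry model

`infer_dosage()` runs a diploid HMM per individual. The hidden state is the
unordered number of P-ancestry copies q ∈ {0, 1, 2}. Per haplotype, ancestry
switches between adjacent SNPs at genetic distance d Morgans (physical
distance × `rec`; uniform map) with probability 1 − e^(−g·d) *into the
stationary distribution* (m, 1 − m); the diploid kernel is the exact
collapse of two independent haplotype chains (for q = 1 the P- and
A-carrying haplotypes are distinguishable). Emissions assume each haplotype
draws its allele from the error-adjusted panel frequency
f′ = (1 − eps)f + eps(1 − f) of its ancestry; the genotype likelihood is the
two-haplotype convolution; missing genotypes emit likelihood 1. Panel
frequencies use add-half smoothing, (alt + 0.5)/(called + 1), so no emission
probability is ever 0 or 1.

Numerical choices: the forward pass rescales at every SNP (no unscaled
products); posteriors are verified to sum to 1 within 1e-10 before use;
chromosome changes restart the chain at the stationary diploid distribution.

The stationary proportion m is itself an output of the analysis, so by
default it is estimated self-consistently: starting from m = 0.5, the
genome-wide mean dosage/2 replaces m until the change is < 1e-4 (≤ 10
rounds). The iteration converges in 3–5 rounds on the default demography.

**Monomorphic-SNP filtering.** For file inputs the pipeline driver
(`run_pipeline()`) removes SNPs monomorphic in any population before
inference, mirroring standard pre-LAI QC of real data. For simulated inputs
the filter defaults off (overridable via `polymorphic_filter`), and the
module-level calibration, the FWER estimator and the acceptance pipelines do
not apply it either: at N = 1000 most between-source fixed differences are
monomorphic within each source sample, and removing them deletes the most
ancestry-informative sites — an artefact of the toy population size
(measured: dosage/truth correlation drops from ~0.96 to ~0.76, the
self-consistent mean acquires a ~+2 percentage-point attenuation bias, and
the driver's injected-locus detection power collapses). With real,
large-N_e data the filter is innocuous.

## The scan and its calibration

The scan statistic is the per-SNP mean P proportion across individuals
(mean dosage / 2). `scan_stats()` summarises it by the genome-wide mean and
population-denominator SD (the n vs n−1 distinction is negligible at array
scale) and thresholds at mean + k·SD, k ∈ {2, 4, 5}; comparisons at the
threshold are strict (>). `call_regions()` reports maximal runs of
consecutive above-threshold SNPs per chromosome, merging runs separated by
< 1 Mb *and* < 5 below-threshold SNPs. The merge rule is a documented choice
("independent regions" is otherwise underdefined); region-count tests use
fixtures on which both the merged and unmerged conventions agree.

`estimate_fwer()` replays the full pipeline on neutral simulations, using
each run's *own* mean and SD for its threshold, and reports the fraction of
runs with ≥ 1 called region. At the published scale (100 runs × 3000
segments) this is the probability of any false region per genome; dividing
by the number of regions observed in real data gives the FDR
(`fdr_from_fwer(0.09, 2)` = 0.045). The test suite runs a desk-scale version
(50 runs × 300 segments) and checks FWER ≤ 0.10 + 3·binomial SE; a smaller
genome can only lower the per-genome error rate, so the bound is conservative
at reduced scale.

## Wright–Fisher ABC for the selection coefficient

The forward model composes, per generation, the deterministic selection
update

p′ = [p² + p(1 − p)(1 − s)] / [p² + 2p(1 − p)(1 − s) + (1 − p)²(1 − 2s)]

(fitnesses 1, 1 − s, 1 − 2s for 2, 1, 0 copies of the favoured allele;
mean-fitness denominator) with binomial resampling of 2N copies. Rejection
ABC draws s from a uniform (0, 1) prior, simulates g generations from p0,
and accepts a draw when the final frequency lands in a ±5% relative window
around the observed frequency; the posterior is summarised by the mean and
the equal-tailed 2.5%/97.5% quantiles of the accepted draws (the paper-style
symmetric interval; the quantile definition is R's default type 7).

Two numerical notes. First, the published recursion's denominator is treated
as the standard mean fitness (its printed form omits a "+", which does not
normalise); a genotype-bookkeeping oracle (Hardy–Weinberg frequencies ×
fitnesses, renormalise) verifies the implementation. Second, a uniform (0,1)
prior proposes s > 0.5, where the TT fitness 1 − 2s would be negative;
the trajectory simulator clamps genotype fitnesses at 0, which keeps every
draw well-defined. Such draws sweep to fixation and can never be accepted by
a sub-unity window, so the posterior is unchanged; the bare `freq_update()`
operation still errors if its denominator is non-positive. Trajectories are
vectorised in batches (default 10,000) without affecting the draw sequence;
identical seeds give identical posteriors.

With the published configuration — p0 = 0.26 (0.915·0.246 + 0.049·0.754),
N = 1000, g = 100, window [0.722, 0.798] around the observed 0.76, 10,000
accepted draws — the posterior concentrates near s ≈ 0.02; the acceptance
script recomputes the exact summaries at run time.

## Two-locus LD

`em_haplotypes()` estimates the four haplotype frequencies from unphased
two-locus genotypes by EM. Only the double heterozygote is phase-ambiguous;
it is split between coupling and repulsion phases in proportion to the
current frequency products. Initialisation is deterministic at linkage
equilibrium (marginal products), which avoids seed dependence; the two-locus
likelihood is unimodal in practice, and the observed-data log-likelihood is
asserted non-decreasing at every iteration. Samples missing at either locus
are dropped. D′ and r² follow the standard Lewontin definitions on the same
haplotype-frequency estimates; D′ is defined as 0 when D = 0, and both
statistics are invariant to allele-label swaps.

## Reproducibility and numerical conventions

* All randomness flows through R's RNG: every public stochastic function
  takes an optional integer `seed` and otherwise continues the caller's
  stream; compiled code uses R's RNG. `estimate_fwer()` derives run i's seed
  as `seed + i − 1`.
* Positions are 1-based and inclusive throughout (VCF convention); missing
  genotypes are `NA` in the TSV dialect and `./.` in VCF; alleles are taken
  as recorded (no strand flipping).
* Monomorphic SNPs are retained by readers; polymorphism requirements live in
  the operations that need them.
* Run configuration files are JSON rather than YAML (no YAML parser among the
  package's allowed dependencies); structure and semantics are unchanged.

## Known limitations

* The generator's missing features listed above (no background LD, no
  post-admixture ancestry drift, no post-split mutations).
* The HMM is a single-layer diploid ancestry model, not a haplotype-cluster
  model; ELAI-specific quantities (e.g. its exact smoothing and the real-data
  SD of 8.63%) are reference constants, not targets.
* Three-way admixture (e.g. a recent European contribution) is an extension
  point, not implemented.
* Real-data results that depend on restricted genotypes (f3 magnitudes,
  genome-wide 24.6%/8.63% as outputs, the chr6/chr16 region coordinates,
  Table-2-style D′/r² values) are not reproducible and are covered only by
  sign, pattern and parameter-recovery properties.
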