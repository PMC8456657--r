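# admixsel

Detecting and quantifying **admixture-enabled selection** — post-admixture
positive selection on variants contributed by one source population of an
admixed population.

## Who this is for

Population geneticists analysing a two-way admixed cohort (the motivating
case is Polynesian-type history: an Asian-related source **A** and a
Papuan-related source **P** admixing ~100 generations ago, with ~24.6% P
ancestry) who want to:

* scan the genome for loci where one ancestry is over-represented relative
  to the genome-wide admixture fraction,
* calibrate that scan's family-wise error rate / FDR against neutral
  simulations of an explicit demography,
* verify the admixture itself (f3 test) and estimate the mixture proportion
  (f4-ratio) with block-jackknife errors,
* estimate the selection coefficient of a candidate allele by rejection ABC
  under a Wright–Fisher forward model, and
* summarise two-locus LD (D′, r²) from unphased genotypes.

## The core models

**Local ancestry.** A diploid HMM over unphased genotypes: hidden state
q ∈ {0, 1, 2} counts P-ancestry copies at a SNP; per haplotype, ancestry
switches over genetic distance *d* Morgans with probability 1 − e^(−g·d)
into the stationary distribution (m, 1 − m); emissions are the two-haplotype
convolution of Bernoulli draws from error-adjusted source-panel frequencies.
The forward–backward posterior gives the expected ancestry dosage
Σ q·Pr(q | data); the per-SNP mean dosage/2 across individuals is the scan
track. m is estimated self-consistently from the genome-wide mean dosage.

**The scan.** Genome-wide mean x̄ and SD s of the track; regions are maximal
runs of SNPs with track > x̄ + k·s (k = 5 by default; with the published
genome-wide summary x̄ = 24.6%, s = 8.63% the 5 SD threshold is 67.8%).
`estimate_fwer()` replays the pipeline on neutral simulations of the
demography (sources split 1667 generations ago, single-pulse admixture 100
generations ago, N = 1000 per population, 1 Mb segments, MAF-matched SNP
ascertainment) and reports how often any region is called; FDR = FWER /
observed region count.

**Selection coefficient.** Generation by generation,
p′ = [p² + p(1−p)(1−s)] / [p² + 2p(1−p)(1−s) + (1−p)²(1−2s)] (genotype
fitnesses 1, 1−s, 1−2s) followed by binomial resampling of 2N copies.
Rejection ABC draws s ~ U(0, 1) and keeps draws whose final frequency lands
within ±5% of the observed frequency.

See `vignettes/admixture-enabled-selection.Rmd` for assumptions, parameter
meanings, numerical choices, and what the synthetic world does and does not
emulate.

## Worked example

Simulate a 60-segment genome with a selected locus (s = 0.03) injected in
segment 30, then run the full scan:

```r
library(admixsel)
cfg <- list(simulate = list(n_segments = 60, target_count = 1800,
                            selected = list(segment = 30, position = 5e5,
                                            s = 0.03)))
report <- run_pipeline(cfg, seed = 11)
print(report)
```

```
== admixture-enabled selection scan ==
scan_summary: mean 0.258, SD 0.0944 over 1800 SNPs
  thresholds: 2SD 0.447 | 4SD 0.636 | 5SD 0.730
  scan threshold (mean + 5 SD): 0.7305
  regions:
 chrom     start       end n_snps  max_prop mean_prop
  chr1 145035024 145967080     25 0.9184328 0.8596083
```

The genome-wide mean P ancestry (25.8%) sits near the simulated admixture
fraction 24.6%; the single region called at mean + 5 SD covers exactly the
injected segment (segment 30 starts at 145 Mb on pseudo-chromosome 1), with
25 above-threshold SNPs peaking at 91.8% P ancestry.

Estimate the selection coefficient for an allele observed at frequency 0.76
that entered the admixed population at p0 = 0.915·0.246 + 0.049·0.754 = 0.26:

```r
post <- abc_estimate(p0 = 0.26, N = 1000, g = 100,
                     window = acceptance_window(0.76, 0.05),
                     n_accept = 10000, seed = 11)
print(post)
```

```
abc_posterior: mean s = 0.0218, 95% CI [0.0125, 0.0310]
  10000 accepted / 2510000 attempts (rate 0.00399)
```

A selection coefficient of ~2% per allele copy is strong positive selection:
enough to move an allele from 26% to ~76% frequency in 100 generations.

## Command line

```sh
admixsel simulate --config demography.json --seed 1 --out simdata/
admixsel infer-ancestry --admixed adm.tsv --ref-p p.tsv --ref-a a.tsv --out dosage.tsv
admixsel scan --dosage dosage.tsv --k 5 --out regions.tsv
admixsel scan-null --runs 100 --config demography.json --seed 1 --out fwer.json
admixsel abc --p0 0.26 --observed 0.76 --tol 0.05 --accepted 10000 --seed 1
admixsel ld --vcf pop.vcf --snp1 chr16:48000000 --snp2 chr16:48200000
admixsel run --config pipeline.json --seed 1 --out out/
```

(`exec/admixsel` is installed with the package; configs are JSON.)

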