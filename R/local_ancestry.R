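#' Ancestry dosage matrix
#'
#' Holds per-individual, per-SNP expected counts of P-ancestry copies (in
#' [0, 2]) and the per-SNP mean P proportion (mean dosage / 2 across
#' individuals), which is the genome-scan track.
#'
#' @param dosage numeric matrix, individuals x SNPs, values in [0, 2].
#' @param snps SNP metadata data frame (`chrom`, `pos`, ...).
#' @param params optional list of inference parameters to carry along.
#' @return an object of class `ancestry_dosage`.
#' @export
ancestry_dosage <- function(dosage, snps, params = NULL) {
  dosage <- as.matrix(dosage)
  if (any(dosage < -1e-9 | dosage > 2 + 1e-9))
    stop("dosage values must lie in [0, 2]")
  structure(list(dosage = dosage,
                 mean_prop = colMeans(dosage) / 2,
                 snps = as.data.frame(snps), params = params),
            class = "ancestry_dosage")
}

#' @export
print.ancestry_dosage <- function(x, ...) {
  cat("ancestry_dosage:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs\n")
  cat(sprintf("  genome-wide mean P proportion: %.4f\n", mean(x$mean_prop)))
  invisible(x)
}

#' Estimate smoothed reference allele frequencies for one source population
#'
#' Per-SNP alternate-allele frequency with add-half smoothing,
#' `(alt_count + 0.5) / (called_alleles + 1)`, so frequencies are never
#' exactly 0 or 1 (the HMM emission model requires this). Missing genotypes
#' are excluded from the counts; a SNP with no called alleles gets frequency
#' 0.5 with a warning.
#'
#' @param gm a [genotype_matrix()] of a reference panel.
#' @return an object of class `allele_freq_panel` with fields `freq` and
#'   `n_called` (called allele count per SNP).
#' @export
estimate_source_freqs <- function(gm) {
  validate_genotype_matrix(gm)
  if (length(gm$samples) == 0) stop("empty genotype matrix")
  alt <- colSums(gm$geno, na.rm = TRUE)
  called <- 2 * colSums(!is.na(gm$geno))
  if (any(called == 0))
    warning(sum(called == 0), " SNP(s) with no called alleles; frequency set to 0.5")
  structure(list(freq = (alt + 0.5) / (called + 1), n_called = called,
                 snps = gm$snps),
            class = "allele_freq_panel")
}

#' HMM parameters for local ancestry inference
#'
#' @param g admixture generations (chain switch intensity per Morgan).
#' @param m stationary P-ancestry proportion; `NULL` (default) estimates m by
#'   self-consistent iteration inside [infer_dosage()].
#' @param rec recombination rate per bp per generation (uniform genetic map).
#' @param eps per-allele genotyping / panel-mislabeling error rate.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(g = 100, m = NULL, rec = 1.3e-8, eps = 0.005) {
  stopifnot(g >= 1, rec > 0, eps >= 0, eps < 0.5)
  if (!is.null(m)) stopifnot(m > 0, m < 1)
  structure(list(g = g, m = m, rec = rec, eps = eps), class = "hmm_params")
}

#' Infer expected P-ancestry dosage from unphased genotypes
#'
#' Runs a diploid hidden Markov model individual by individual over the
#' admixed genotypes. The hidden state is the unordered count of P-ancestry
#' copies (0, 1, 2); each haplotype switches ancestry between adjacent SNPs
#' at genetic distance d Morgans with probability `1 - exp(-g d)` into the
#' stationary distribution `(m, 1 - m)`, and emits alleles as Bernoulli
#' draws from the error-adjusted frequency of its ancestry's panel.
#' Chromosomes are treated as independent. The forward-backward pass uses
#' per-site rescaling and the posterior expected dosage
#' `sum_q q P(q | data)` is returned.
#'
#' If `params$m` is `NULL`, m is estimated by self-consistent iteration:
#' starting from m = 0.5, the genome-wide mean dosage / 2 replaces m until
#' the change drops below 1e-4 (at most 10 rounds).
#'
#' @param gm_admixed a [genotype_matrix()] of the admixed individuals.
#' @param panel_P,panel_A [estimate_source_freqs()] panels for sources P
#'   and A, on the identical SNP set.
#' @param params an [hmm_params()] object.
#' @return an `ancestry_dosage` object; `$params` records the final m, the
#'   number of m iterations and the total log-likelihood.
#' @export
infer_dosage <- function(gm_admixed, panel_P, panel_A, params = hmm_params()) {
  validate_genotype_matrix(gm_admixed)
  stopifnot(inherits(panel_P, "allele_freq_panel"),
            inherits(panel_A, "allele_freq_panel"),
            inherits(params, "hmm_params"))
  S <- n_snps(gm_admixed)
  if (length(panel_P$freq) != S || length(panel_A$freq) != S)
    stop("reference panels and admixed genotypes must cover the same SNPs")
  if (!is.null(panel_P$snps) &&
      !identical(panel_P$snps$pos, gm_admixed$snps$pos))
    stop("reference panels and admixed genotypes must cover the same SNPs")
  if (S == 0) stop("no SNPs to analyse")

  chrom_id <- as.integer(factor(gm_admixed$snps$chrom,
                                levels = unique(gm_admixed$snps$chrom)))
  geno <- t(gm_admixed$geno) # snps x individuals

  run <- function(m) {
    hmm_dosage_cpp(geno, panel_P$freq, panel_A$freq,
                   as.numeric(gm_admixed$snps$pos), chrom_id,
                   params$g, m, params$rec, params$eps)
  }
  if (!is.null(params$m)) {
    m <- params$m
    fit <- run(m)
    iters <- 0L
  } else {
    m <- 0.5
    for (iters in seq_len(10)) {
      fit <- run(m)
      m_new <- min(max(mean(fit$dosage) / 2, 1e-4), 1 - 1e-4)
      done <- abs(m_new - m) < 1e-4
      m <- m_new
      if (done) break
    }
    fit <- run(m)
  }
  dosage <- t(fit$dosage)
  rownames(dosage) <- gm_admixed$samples
  ancestry_dosage(dosage, gm_admixed$snps,
                  params = list(g = params$g, m = m, rec = params$rec,
                                eps = params$eps, m_iterations = iters,
                                loglik = fit$loglik,
                                max_posterior_dev = fit$max_posterior_dev))
}

#' Per-SNP mean ancestry proportion track
#'
#' The scan statistic: at each SNP, the mean of dosage / 2 across
#' individuals, i.e. the estimated proportion of P-derived chromosomes.
#'
#' @param dm an `ancestry_dosage` object.
#' @return numeric vector of length = SNP count.
#' @export
mean_ancestry_track <- function(dm) {
  stopifnot(inherits(dm, "ancestry_dosage"))
  if (nrow(dm$dosage) < 1) stop("need at least one individual")
  dm$mean_prop
}
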