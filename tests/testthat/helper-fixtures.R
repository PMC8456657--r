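# Shared fixtures, built once per test run and cached. All seeds are fixed
# up front; heavy simulations are scaled down relative to the study's 3000
# segments (noted where a test depends on the scale).

fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# 300-segment neutral dataset (1/10 of the study genome), ascertained to the
# proportional SNP target; used for calibration, accuracy and the scaled
# acceptance criteria.
default_sim <- function() {
  get_fixture("default_sim", function() {
    cfg <- demography_config(n_segments = 300)
    ds <- simulate_neutral(cfg, seed = 20240901)
    suppressWarnings(ascertain_snps(ds, min(16236, n_snps(ds$admixed))))
  })
}

default_dosage <- function() {
  get_fixture("default_dosage", function() {
    ds <- default_sim()
    infer_dosage(ds$admixed, estimate_source_freqs(ds$P),
                 estimate_source_freqs(ds$A), hmm_params())
  })
}

# 60-segment dataset with an outgroup at the root, for the f-statistics
# recovery properties (>= 1e4 SNPs).
fstats_sim <- function() {
  get_fixture("fstats_sim", function() {
    cfg <- demography_config(n_segments = 150, include_outgroup = TRUE)
    simulate_neutral(cfg, seed = 20240902)
  })
}

fstats_table <- function() {
  get_fixture("fstats_table", function() {
    ds <- fstats_sim()
    # split source A's sample into two proxy panels (A1 ~ "CHB", A2 ~ "Taiwan")
    half <- seq_len(22)
    a1 <- genotype_matrix(ds$A$samples[half], ds$A$snps,
                          ds$A$geno[half, , drop = FALSE])
    a2 <- genotype_matrix(ds$A$samples[-half], ds$A$snps,
                          ds$A$geno[-half, , drop = FALSE])
    freq_table(list(ADM = ds$admixed, P = ds$P, A1 = a1, A2 = a2, O = ds$O))
  })
}

# small genotype_matrix builder for unit fixtures
toy_gm <- function(geno, pos = NULL, chrom = "chr1",
                   samples = sprintf("s%d", seq_len(nrow(geno)))) {
  geno <- as.matrix(geno)
  if (is.null(pos)) pos <- seq_len(ncol(geno)) * 1000L
  snps <- data.frame(chrom = rep_len(chrom, ncol(geno)), pos = as.integer(pos),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(samples, snps, geno)
}

# minimal sim_dataset wrapper around a designed admixed genotype matrix, for
# exercising ascertainment allocation against hand-built MAF distributions
toy_sim_dataset <- function(gm_admixed, segment = NULL) {
  n_hap <- 2 * length(gm_admixed$samples)
  empty <- genotype_matrix(character(0), gm_admixed$snps,
                           matrix(integer(0), 0, n_snps(gm_admixed)))
  structure(list(
    P = empty, admixed = gm_admixed, A = empty,
    true_ancestry = matrix(0L, n_hap, n_snps(gm_admixed)),
    segment = segment %||% rep(1L, n_snps(gm_admixed)),
    freqs = list(P_adm = rep(0.5, n_snps(gm_admixed)),
                 A_adm = rep(0.5, n_snps(gm_admixed)),
                 P_now = rep(0.5, n_snps(gm_admixed)),
                 A_now = rep(0.5, n_snps(gm_admixed))),
    config = demography_config(n_segments = max(segment %||% 1L)),
    seed = NULL
  ), class = "sim_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# frequency panel built directly from numbers (bypassing genotype counting)
toy_panel <- function(freq) {
  structure(list(freq = freq, n_called = rep(100L, length(freq)), snps = NULL),
            class = "allele_freq_panel")
}
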