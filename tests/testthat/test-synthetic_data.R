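small_cfg <- function(...) demography_config(n_segments = 2, ...)

test_that("degenerate demographies behave as stated", {
  # alpha_P = 0: every label A, admixed frequencies track source A
  ds <- simulate_neutral(small_cfg(alpha_P = 0), seed = 101)
  expect_true(all(ds$true_ancestry == 0L))
  f_adm <- colMeans(ds$admixed$geno) / 2
  f_a <- colMeans(ds$A$geno) / 2
  # admixed copies source A at admixture time; differences reflect 100
  # generations of drift plus sampling
  drift_sd <- sqrt(pmax(f_a * (1 - f_a), 0.25 / 45) *
                     (100 / 2000 + 1 / 45 + 1 / 23))
  expect_lt(mean(abs(f_adm - f_a) / pmax(drift_sd, 0.05)), 2)

  # alpha_P = 1: all-P labels, all-two true dosage
  ds1 <- simulate_neutral(small_cfg(alpha_P = 1), seed = 102)
  expect_true(all(ds1$true_ancestry == 1L))
  expect_true(all(true_dosage(ds1)$dosage == 2L))

  # mu = 0: no segregating sites
  ds0 <- simulate_neutral(small_cfg(mu = 0), seed = 103)
  expect_equal(n_snps(ds0$admixed), 0)

  # sample size beyond 2N errors
  expect_error(demography_config(N = 20,
                                 sample_chromosomes = c(P = 48, admixed = 46,
                                                        A = 90)),
               "exceeds 2N")
})

test_that("simulated SNPs are polymorphic in the pooled sample and sorted", {
  ds <- simulate_neutral(small_cfg(), seed = 104)
  cnt <- colSums(ds$P$geno) + colSums(ds$admixed$geno) + colSums(ds$A$geno)
  tot <- 2 * (length(ds$P$samples) + length(ds$admixed$samples) +
                length(ds$A$samples))
  expect_true(all(cnt > 0 & cnt < tot))
  expect_silent(validate_genotype_matrix(ds$admixed))
  expect_equal(dim(ds$true_ancestry), c(46, n_snps(ds$admixed)))
})

test_that("mean P ancestry matches alpha_P (replicate-mean oracle)", {
  # one default segment, 50 replicate seeds: the replicate mean must sit
  # within 3 SE of alpha_P, with the SE taken from the replicates themselves
  cfg <- demography_config(n_segments = 1)
  means <- vapply(1:50, function(i) {
    mean(simulate_neutral(cfg, seed = 200 + i)$true_ancestry)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.246), 3 * se)
})

test_that("genome-wide ancestry converges at 300 segments (within 2%)", {
  ds <- default_sim()
  expect_lt(abs(mean(ds$true_ancestry) - 0.246), 0.02)
})

test_that("segments are statistically independent", {
  cfg <- demography_config(n_segments = 2)
  pairs <- do.call(rbind, lapply(1:30, function(i) {
    ds <- simulate_neutral(cfg, seed = 300 + i)
    i1 <- which(ds$segment == 1)[1]
    i2 <- which(ds$segment == 2)[1]
    cbind(ds$true_ancestry[, i1], ds$true_ancestry[, i2])
  }))
  r <- cor(pairs[, 1], pairs[, 2])
  expect_lt(abs(r), 3 / sqrt(nrow(pairs)))
})

test_that("mean complete P-tract length matches 1/(g(1-alpha)) within 15%", {
  set.seed(42)
  lens <- unlist(lapply(1:200, function(i) {
    tr <- simulate_ancestry_tracts(1.3, 100, 0.246)
    # complete tracts only (not censored by the window edges)
    keep <- tr$ancestry == 1 & tr$start > 0 & tr$end < 1.3
    tr$end[keep] - tr$start[keep]
  }))
  expected <- 1 / (100 * (1 - 0.246))
  expect_gt(length(lens), 1000)
  expect_lt(abs(mean(lens) - expected) / expected, 0.15)
})

test_that("ascertainment follows the largest-remainder allocation", {
  # designed MAF distribution: 10 diploids, alt counts 1..10 -> MAF bins 1..10
  per_bin <- c(150, 130, 120, 110, 100, 95, 90, 85, 70, 50) # 1000 SNPs
  counts <- rep(1:10, per_bin)
  g <- vapply(counts, function(k) {
    v <- integer(10)
    v[seq_len(floor(k / 2))] <- 2L
    if (k %% 2 == 1) v[floor(k / 2) + 1] <- 1L
    v
  }, integer(10))
  ds <- toy_sim_dataset(toy_gm(g))
  w <- c(2, 1, 1, 1, 1, 1, 1, 1, 0.5, 0.5)
  out <- ascertain_snps(ds, 500, maf_reference = w, seed = 5)
  f <- colMeans(out$admixed$geno) / 2
  got <- tabulate(ceiling(pmin(f, 1 - f) / 0.05), nbins = 10)
  expect_equal(got, allocation_oracle(500, w))
  expect_equal(n_snps(out$admixed), 500)

  # target = available with uniform-by-construction bins -> identity up to order
  per_bin_u <- rep(100, 10)
  counts_u <- rep(1:10, per_bin_u)
  gu <- vapply(counts_u, function(k) {
    v <- integer(10)
    v[seq_len(floor(k / 2))] <- 2L
    if (k %% 2 == 1) v[floor(k / 2) + 1] <- 1L
    v
  }, integer(10))
  dsu <- toy_sim_dataset(toy_gm(gu))
  outu <- ascertain_snps(dsu, 1000, seed = 6)
  expect_equal(sort(outu$admixed$snps$pos), sort(dsu$admixed$snps$pos))

  # mass confined to the top bin -> every retained SNP has MAF > 0.4
  out2 <- ascertain_snps(ds, 40, maf_reference = c(rep(0, 9), 1), seed = 7)
  f2 <- colMeans(out2$admixed$geno) / 2
  expect_true(all(pmin(f2, 1 - f2) > 0.4))

  # exhausted bin warns; empty reference errors
  expect_warning(ascertain_snps(ds, 900, maf_reference = c(rep(0, 9), 1),
                                seed = 8),
                 "exhausted")
  expect_error(ascertain_snps(ds, 10, maf_reference = numeric(0)), "bin mass")
  expect_error(ascertain_snps(ds, 2000), "exceeds available")
})

test_that("true_dosage is the haplotype-label sum", {
  ds <- simulate_neutral(small_cfg(), seed = 105)
  td <- true_dosage(ds)
  expect_true(all(td$dosage %in% 0:2))
  expect_equal(mean(td$dosage) / 2, mean(ds$true_ancestry))
  expect_equal(td$mean_prop, colMeans(ds$true_ancestry))
})

test_that("injected selection drives the favoured allele up (trajectory oracle)", {
  # find a base dataset whose focal SNP starts near p0 = 0.26
  base <- NULL
  for (seed in 400:420) {
    ds <- simulate_neutral(demography_config(n_segments = 3), seed = seed)
    probe <- inject_selected_locus(ds, selected_locus_spec(2, 5e5, 0), seed = 1)
    if (abs(probe$selected$p0 - 0.26) < 0.04) { base <- ds; break }
  }
  expect_false(is.null(base))

  probe0 <- inject_selected_locus(base, selected_locus_spec(2, 5e5, 0),
                                  seed = 1)$selected$p0
  finals <- vapply(1:50, function(i) {
    inject_selected_locus(base, selected_locus_spec(2, 5e5, 0.02),
                          seed = 500 + i)$selected$final_freq
  }, numeric(1))
  # Monte-Carlo oracle from the abc-module trajectory simulator, at the
  # realised founder frequency
  oracle_finals <- simulate_trajectories(rep(0.02, 400), 1000, 100, probe0,
                                         seed = 99)
  p_band_oracle <- mean(oracle_finals >= 0.6 & oracle_finals <= 0.9)
  p_band <- mean(finals >= 0.6 & finals <= 0.9)
  # the oracle puts most mass in [0.6, 0.9]; the injector must agree with the
  # oracle's band probability within Monte-Carlo error
  expect_gt(p_band_oracle, 0.75)
  expect_lt(abs(p_band - p_band_oracle),
            3 * sqrt(p_band_oracle * (1 - p_band_oracle) / 50 + 0.25 / 400))
  # and agree in location
  expect_lt(abs(mean(finals) - mean(oracle_finals)),
            3 * sqrt(var(finals) / 50 + var(oracle_finals) / 400) + 0.02)

  # focal-SNP P ancestry exceeds the genome-wide mean in >= 95% of seeds
  anc_gain <- vapply(1:50, function(i) {
    ds2 <- inject_selected_locus(base, selected_locus_spec(2, 5e5, 0.02),
                                 seed = 500 + i)
    td <- true_dosage(ds2)
    mean(td$dosage[, ds2$selected$snp_index]) / 2 - mean(td$dosage) / 2
  }, numeric(1))
  expect_gte(mean(anc_gain > 0), 0.95)

  # s = 0 leaves the focal scan statistic inside the neutral band
  neutral_anc <- vapply(1:20, function(i) {
    ds2 <- inject_selected_locus(base, selected_locus_spec(2, 5e5, 0),
                                 seed = 600 + i)
    td <- true_dosage(ds2)
    mean(td$dosage[, ds2$selected$snp_index]) / 2
  }, numeric(1))
  # null band: binomial sampling of 46 haplotypes around alpha_P
  band <- 2 * sqrt(0.246 * 0.754 / 46)
  expect_lt(abs(mean(neutral_anc) - 0.246), band)

  expect_error(selected_locus_spec(1, 1, 0.6), "s")
})

test_that("simulation is reproducible under a fixed seed", {
  a <- simulate_neutral(small_cfg(), seed = 77)
  b <- simulate_neutral(small_cfg(), seed = 77)
  expect_identical(a$admixed$geno, b$admixed$geno)
  expect_identical(a$true_ancestry, b$true_ancestry)
})
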