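test_that("scan_stats reproduces the printed-summary arithmetic", {
  # a two-point track has exactly the given mean and population SD
  st <- scan_stats(c(24.6 - 8.63, 24.6 + 8.63) / 100)
  expect_equal(st$mean, 0.246)
  expect_equal(st$sd, 0.0863)
  expect_equal(unname(st$thresholds["k5"]), 0.6775)
  expect_equal(sprintf("%.1f", 100 * st$thresholds["k5"]), "67.8")

  st2 <- scan_stats(rep(0.3, 10))
  expect_equal(st2$sd, 0)
  expect_equal(unname(st2$thresholds), rep(0.3, 3))

  x <- c(0.1, 0.2, 0.25, 0.4, 0.55)
  st3 <- scan_stats(x)
  expect_equal(st3$mean, mean(x))
  expect_equal(st3$sd, sqrt(mean((x - mean(x))^2)))
  expect_equal(unname(st3$thresholds["k4"]), mean(x) + 4 * st3$sd)
  expect_error(scan_stats(numeric(0)), "at least 2")
})

test_that("call_regions applies the run/merge rules", {
  pos <- c(1e6, 2e6, 3e6, 4e6, 5e6, 6e6, 7e6, 8e6)
  chrom <- rep("chr1", 8)

  expect_equal(nrow(call_regions(rep(0.1, 8), pos, chrom, 0.5)), 0)

  # two runs separated by 2 Mb (and >= 5 below-threshold SNPs) -> two regions
  tr <- c(0.9, 0.9, rep(0.1, 5), 0.9)
  pos2 <- c(1e6, 1.1e6, 1.2e6, 1.3e6, 1.4e6, 1.5e6, 1.6e6, 3.2e6)
  reg2 <- call_regions(tr, pos2, chrom, 0.5)
  expect_equal(nrow(reg2), 2)
  expect_equal(reg2$start, c(1e6, 3.2e6))
  expect_equal(reg2$end, c(1.1e6, 3.2e6))
  expect_equal(reg2$n_snps, c(2L, 1L))

  # two runs separated by 200 kb and 2 intervening SNPs -> one region
  tr3 <- c(0.9, 0.9, 0.1, 0.1, 0.9, 0.9, 0.1, 0.1)
  pos3 <- c(1e6, 1.05e6, 1.1e6, 1.15e6, 1.2e6, 1.25e6, 2e7, 3e7)
  reg3 <- call_regions(tr3, pos3, chrom, 0.5)
  expect_equal(nrow(reg3), 1)
  expect_equal(reg3$start, 1e6)
  expect_equal(reg3$end, 1.25e6)
  expect_equal(reg3$n_snps, 4L) # above-threshold SNPs only

  # strictly-greater comparison at the threshold
  expect_equal(nrow(call_regions(c(0.5, 0.5), pos[1:2], chrom[1:2], 0.5)), 0)

  # regions never span chromosomes, and output is order-invariant
  tr4 <- c(0.9, 0.9, 0.9, 0.9)
  pos4 <- c(1e6, 1.1e6, 1e6, 1.1e6)
  ch4 <- c("chr1", "chr1", "chr2", "chr2")
  reg4 <- call_regions(tr4, pos4, ch4, 0.5)
  expect_equal(nrow(reg4), 2)
  reg4b <- call_regions(rev(tr4), rev(pos4), rev(ch4), 0.5)
  expect_equal(nrow(reg4b), 2)
  expect_setequal(reg4$chrom, reg4b$chrom)

  # constant track at threshold = mean -> nothing called;
  # a spike above any threshold -> called
  st <- scan_stats(rep(0.25, 6))
  expect_equal(nrow(call_regions(rep(0.25, 6), pos[1:6], chrom[1:6],
                                 unname(st$thresholds["k5"]))), 0)
  expect_equal(nrow(call_regions(c(0.25, 0.99, 0.25), pos[1:3], chrom[1:3],
                                 0.9)), 1)
})

test_that("fdr_from_fwer is the stated ratio", {
  expect_equal(fdr_from_fwer(0.09, 2), 0.045)
  expect_equal(fdr_from_fwer(0, 7), 0)
  expect_equal(fdr_from_fwer(0.5, 5), 0.1)
  expect_error(fdr_from_fwer(0.09, 0), "zero observed")
})

test_that("estimate_fwer runs the pipeline per run and is reproducible", {
  cfg <- demography_config(n_segments = 15)
  fw <- estimate_fwer(2, cfg, seed = 31, target_count = 400)
  expect_length(fw$region_counts, 2)
  expect_true(fw$fwer >= 0 && fw$fwer <= 1)
  expect_equal(fw$fwer, mean(fw$region_counts >= 1))
  fw2 <- estimate_fwer(2, cfg, seed = 31, target_count = 400)
  expect_identical(fw$region_counts, fw2$region_counts)
})

test_that("scan power: injected selection is detected and rises with s", {
  cfg <- demography_config(n_segments = 100)
  detect_focal <- function(s, seed) {
    ds <- simulate_neutral(cfg, seed = seed)
    ds <- inject_selected_locus(ds, selected_locus_spec(50, 5e5, s))
    ds <- suppressWarnings(ascertain_snps(ds, min(5400, n_snps(ds$admixed))))
    dm <- infer_dosage(ds$admixed, estimate_source_freqs(ds$P),
                       estimate_source_freqs(ds$A), hmm_params())
    track <- mean_ancestry_track(dm)
    st <- scan_stats(track)
    reg <- call_regions(track, ds$admixed$snps$pos, ds$admixed$snps$chrom,
                        st$mean + 5 * st$sd)
    if (nrow(reg) == 0) return(FALSE)
    focal_start <- (50 - 1) %% 150 * 5e6
    any(reg$chrom == "chr1" & reg$end >= focal_start &
          reg$start <= focal_start + 1e6)
  }
  svals <- c(0, 0.01, 0.02, 0.04)
  nseeds <- c(10, 10, 20, 10)
  power <- vapply(seq_along(svals), function(k) {
    mean(vapply(seq_len(nseeds[k]),
                function(i) detect_focal(svals[k], 700 + 30 * k + i),
                logical(1)))
  }, numeric(1))
  # majority detection at s = 0.02 (20 seeds) and monotone power in s within
  # Monte-Carlo slack
  expect_gt(power[3], 0.5)
  expect_gte(power[4], power[1])
  slack <- 2 * sqrt(0.25 / 10)
  expect_true(all(diff(power) >= -slack))
})
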