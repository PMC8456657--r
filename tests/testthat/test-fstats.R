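# hand-built frequency table for the arithmetic oracles
toy_ft <- function(freqs, n = 40) {
  ft <- data.frame(chrom = "chr1", pos = seq_len(nrow(freqs)) * 1000)
  for (nm in colnames(freqs)) {
    ft[[paste0("freq_", nm)]] <- freqs[, nm]
    ft[[paste0("n_", nm)]] <- n
  }
  class(ft) <- c("freq_table", "data.frame")
  ft
}

test_that("f3 matches the per-SNP arithmetic oracle on a 4-SNP toy table", {
  fr <- cbind(C = c(0.50, 0.20, 0.70, 0.40),
              A = c(0.10, 0.30, 0.90, 0.40),
              B = c(0.90, 0.10, 0.50, 0.40))
  ft <- toy_ft(fr, n = 40)
  terms <- (fr[, "C"] - fr[, "A"]) * (fr[, "C"] - fr[, "B"]) -
    fr[, "C"] * (1 - fr[, "C"]) / (40 - 1)
  r <- f3(ft, "C", "A", "B", block_size = 2)
  expect_equal(r$value, mean(terms))
  expect_equal(r$n_snps, 4)

  # C identical to A with correction disabled -> exactly 0
  fr0 <- cbind(C = c(0.2, 0.5, 0.8), A = c(0.2, 0.5, 0.8), B = c(0.9, 0.1, 0.3))
  r0 <- f3(toy_ft(fr0), "C", "A", "B", block_size = 1, correction = FALSE)
  expect_equal(r0$value, 0)

  # symmetry in the two sources
  expect_equal(f3(ft, "C", "A", "B", block_size = 2)$value,
               f3(ft, "C", "B", "A", block_size = 2)$value)
})

test_that("f3 with correction is invariant to allele-label flips", {
  set.seed(13)
  fr <- cbind(C = runif(20), A = runif(20), B = runif(20))
  flip <- sample(c(TRUE, FALSE), 20, TRUE)
  fr2 <- fr
  fr2[flip, ] <- 1 - fr2[flip, ]
  expect_equal(f3(toy_ft(fr), "C", "A", "B", block_size = 5)$value,
               f3(toy_ft(fr2), "C", "A", "B", block_size = 5)$value)
})

test_that("f4 identities: zero when C = D, antisymmetry under swaps", {
  set.seed(14)
  fr <- cbind(A = runif(12), B = runif(12), C = runif(12), D = runif(12))
  ft <- toy_ft(fr)
  ftCC <- toy_ft(cbind(fr, D2 = fr[, "C"]))
  expect_equal(f4(ftCC, "A", "B", "C", "D2", block_size = 3)$value, 0)
  expect_equal(f4(ft, "A", "B", "D", "C", block_size = 3)$value,
               -f4(ft, "A", "B", "C", "D", block_size = 3)$value)
  expect_equal(f4(ft, "B", "A", "C", "D", block_size = 3)$value,
               -f4(ft, "A", "B", "C", "D", block_size = 3)$value)
  expect_equal(f4(ft, "A", "B", "C", "D", block_size = 3)$value,
               mean((fr[, "A"] - fr[, "B"]) * (fr[, "C"] - fr[, "D"])))
})

test_that("block jackknife matches hand computation and the iid-normal oracle", {
  # identical per-block means -> SE 0
  expect_equal(block_jackknife(rep(c(1, 2), 10), block_size = 2)$se, 0)

  # two unequal blocks, fully hand-computed weighted (Busing) jackknife
  x <- c(1, 2, 3, 10, 20)
  jk <- block_jackknife(x, block_size = 3)
  n <- 5; m_j <- c(3, 2); g <- 2
  theta <- mean(x)
  theta_j <- c(mean(x[4:5]), mean(x[1:3]))
  h <- n / m_j
  theta_J <- g * theta - sum((1 - m_j / n) * theta_j)
  tau <- h * theta - (h - 1) * theta_j
  expect_equal(jk$estimate, theta)
  expect_equal(jk$se, sqrt(mean((tau - theta_J)^2 / (h - 1))))

  # iid normal terms: jackknife SE within 20% of sd/sqrt(n), on average
  set.seed(15)
  ratio <- replicate(100, {
    z <- rnorm(1000)
    block_jackknife(z, block_size = 50)$se / (sd(z) / sqrt(1000))
  })
  expect_lt(abs(mean(ratio) - 1), 0.2)

  expect_error(block_jackknife(1:10, block_size = 10), "block_size")
})

test_that("simulated admixed target gives f3 < 0 with Z < -3", {
  ft <- fstats_table()
  expect_gt(nrow(ft), 1e4)
  r <- f3(ft, "ADM", "A1", "P", block_size = 500)
  expect_lt(r$value, 0)
  expect_lt(r$z, -3)
})

test_that("non-admixed target gives f3 >= 0 within 2 SE", {
  ft <- fstats_table()
  r <- f3(ft, "A2", "A1", "P", block_size = 500)
  expect_gt(r$value, -2 * r$se)
})

test_that("f4-ratio recovers the A-side admixture proportion 0.754", {
  ft <- fstats_table()
  r <- f4_ratio(ft, c("A1", "O", "ADM", "P"), c("A1", "O", "A2", "P"),
                block_size = 500)
  # At N = 1000 the admixed lineages leave the A branch g = 100 generations
  # before the present, so the ratio estimates alpha_A scaled by the shared
  # drift fraction F(t_split - g) / F(t_split), F(t) = 1 - exp(-t / 2N)
  # (negligible for human-scale N_e, ~4% here).
  shrink <- (1 - exp(-1567 / 2000)) / (1 - exp(-1667 / 2000))
  expect_lt(abs(r$value - 0.754 * shrink), 2 * r$se)
  expect_lt(abs(r$value - 0.754), 0.05)
  expect_gt(r$se, 0)

  # target equal to the denominator's source proxy -> alpha = 1
  r1 <- f4_ratio(ft, c("A1", "O", "A2", "P"), c("A1", "O", "A2", "P"),
                 block_size = 500)
  expect_equal(r1$value, 1)
  # target equal to the P-side source -> alpha = 0
  r0 <- f4_ratio(ft, c("A1", "O", "P", "P"), c("A1", "O", "A2", "P"),
                 block_size = 500)
  expect_equal(r0$value, 0)
})

test_that("freq_table computes raw sample frequencies with missing data", {
  g <- rbind(c(0L, 2L), c(1L, NA), c(2L, 2L))
  ft <- freq_table(list(X = toy_gm(g)))
  expect_equal(ft$freq_X, c(3 / 6, 4 / 4))
  expect_equal(ft$n_X, c(6, 4))
  expect_error(freq_table(list(X = toy_gm(g), Y = toy_gm(g[, 1, drop = FALSE]))),
               "same SNP set")
})
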