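# Independent oracles: brute-force / closed-form implementations kept
# deliberately separate from the package's algorithms.

# Exhaustive path enumeration for the diploid ancestry HMM, one individual.
# Sums over all 3^S hidden-state paths; usable for S <= 6.
hmm_enum_oracle <- function(geno, fP, fA, pos, g, m, rec, eps) {
  S <- length(geno)
  adj <- function(f) (1 - eps) * f + eps * (1 - f)
  emit <- function(t, q) {
    gt <- geno[t]
    if (is.na(gt)) return(1)
    p1 <- adj(fP[t]); a1 <- adj(fA[t])
    if (q == 0) dbinom(gt, 2, a1)
    else if (q == 2) dbinom(gt, 2, p1)
    else c((1 - p1) * (1 - a1), p1 * (1 - a1) + (1 - p1) * a1, p1 * a1)[gt + 1]
  }
  hap_T <- function(d) {
    r <- 1 - exp(-g * d * rec)
    matrix(c((1 - r) + r * (1 - m), r * m,
             r * (1 - m), (1 - r) + r * m), 2, 2, byrow = TRUE)
  }
  dip_T <- function(d) {
    Th <- hap_T(d)
    Td <- matrix(0, 3, 3)
    # state q = number of P haplotypes; for q = 1 the chains are distinguishable
    Td[1, ] <- c(Th[1, 1]^2, 2 * Th[1, 1] * Th[1, 2], Th[1, 2]^2)
    Td[2, ] <- c(Th[2, 1] * Th[1, 1], Th[2, 2] * Th[1, 1] + Th[2, 1] * Th[1, 2],
                 Th[2, 2] * Th[1, 2])
    Td[3, ] <- c(Th[2, 1]^2, 2 * Th[2, 2] * Th[2, 1], Th[2, 2]^2)
    Td
  }
  init <- c((1 - m)^2, 2 * m * (1 - m), m^2)
  paths <- as.matrix(expand.grid(rep(list(0:2), S)))
  probs <- apply(paths, 1, function(q) {
    pr <- init[q[1] + 1] * emit(1, q[1])
    if (S > 1) for (t in 2:S) {
      Td <- dip_T(pos[t] - pos[t - 1])
      pr <- pr * Td[q[t - 1] + 1, q[t] + 1] * emit(t, q[t])
    }
    pr
  })
  probs <- probs / sum(probs)
  vapply(seq_len(S), function(t) sum(probs * paths[, t]), numeric(1))
}

# Observed-data log-likelihood of two-locus genotype counts given haplotype
# frequencies (h11, h10, h01, h00); counts is a 3x3 table [g1+1, g2+1].
ld_loglik_oracle <- function(counts, h) {
  pr <- matrix(0, 3, 3)
  pr[3, 3] <- h[1]^2
  pr[3, 2] <- 2 * h[1] * h[2]
  pr[3, 1] <- h[2]^2
  pr[2, 3] <- 2 * h[1] * h[3]
  pr[2, 2] <- 2 * (h[1] * h[4] + h[2] * h[3])
  pr[2, 1] <- 2 * h[2] * h[4]
  pr[1, 3] <- h[3]^2
  pr[1, 2] <- 2 * h[3] * h[4]
  pr[1, 1] <- h[4]^2
  sum(counts[counts > 0] * log(pr[counts > 0]))
}

# grid maximisation of the two-locus likelihood over the haplotype simplex
ld_grid_oracle <- function(counts, step = 0.02, refine = TRUE) {
  grid <- expand.grid(h11 = seq(0, 1, step), h10 = seq(0, 1, step),
                      h01 = seq(0, 1, step))
  grid <- grid[grid$h11 + grid$h10 + grid$h01 <= 1, ]
  ll <- apply(grid, 1, function(r)
    ld_loglik_oracle(counts, c(r[1], r[2], r[3], 1 - sum(r))))
  best <- grid[which.max(ll), ]
  if (refine) {
    fine <- 5e-4
    rng <- function(x) seq(max(0, x - step), min(1, x + step), fine)
    grid2 <- expand.grid(h11 = rng(best$h11), h10 = rng(best$h10),
                         h01 = rng(best$h01))
    grid2 <- grid2[grid2$h11 + grid2$h10 + grid2$h01 <= 1, ]
    ll2 <- apply(grid2, 1, function(r)
      ld_loglik_oracle(counts, c(r[1], r[2], r[3], 1 - sum(r))))
    return(max(ll2))
  }
  max(ll)
}

# post-selection allele frequency by explicit genotype bookkeeping
freq_update_oracle <- function(p, s) {
  gf <- c(p^2, 2 * p * (1 - p), (1 - p)^2) * c(1, 1 - s, 1 - 2 * s)
  gf <- gf / sum(gf)
  gf[1] + gf[2] / 2
}

# largest-remainder integer allocation (independent re-derivation)
allocation_oracle <- function(target, weights) {
  q <- target * weights / sum(weights)
  base <- floor(q)
  frac <- q - base
  need <- target - sum(base)
  if (need > 0) {
    pick <- order(-frac, seq_along(q))[seq_len(need)]
    base[pick] <- base[pick] + 1
  }
  as.integer(base)
}
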