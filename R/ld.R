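#' Two-locus genotype container
#'
#' Pairs of unphased genotypes (alternate-allele counts 0/1/2, `NA` missing)
#' at two loci for a set of samples. Samples missing at either locus are
#' dropped by the EM (complete-case).
#'
#' @param g1,g2 integer vectors of equal length with values in
#'   `{0, 1, 2, NA}`.
#' @return an object of class `two_locus_genotypes`.
#' @export
two_locus_genotypes <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  chk <- function(g) all(is.na(g) | (g >= 0 & g <= 2))
  if (!chk(g1) || !chk(g2)) stop("genotypes must be 0, 1, 2 or NA")
  complete <- !is.na(g1) & !is.na(g2)
  if (sum(complete) < 2) stop("need at least 2 complete samples")
  structure(list(g1 = as.integer(g1), g2 = as.integer(g2)),
            class = "two_locus_genotypes")
}

#' EM estimation of two-locus haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies under random mating. Only the
#' double heterozygote is phase-ambiguous; the EM splits it between the
#' coupling (1-1 / 0-0) and repulsion (1-0 / 0-1) phases in proportion to
#' the current frequency products. Initialisation is deterministic at
#' linkage equilibrium (products of the marginal allele frequencies);
#' convergence when the largest haplotype-frequency change drops below
#' `tol`. The observed-data log-likelihood is non-decreasing across
#' iterations (recorded in `loglik_trace`).
#'
#' @param tg a [two_locus_genotypes()] object.
#' @param tol convergence tolerance on haplotype frequencies.
#' @param max_iter maximum EM iterations (warning on non-convergence).
#' @return an object of class `ld_result`: `haplotypes` (named `h11`, `h10`,
#'   `h01`, `h00` for alt/ref combinations at locus 1-locus 2), `D`,
#'   `Dprime`, `r2`, `iterations`, `loglik`, `loglik_trace`.
#' @export
em_haplotypes <- function(tg, tol = 1e-8, max_iter = 1000) {
  stopifnot(inherits(tg, "two_locus_genotypes"))
  ok <- !is.na(tg$g1) & !is.na(tg$g2)
  g1 <- tg$g1[ok]; g2 <- tg$g2[ok]
  n <- length(g1)
  if (length(unique(g1)) == 1 || length(unique(g2)) == 1)
    stop("monomorphic locus among complete samples; ",
         "report the allele frequency instead of LD")
  counts <- matrix(0, 3, 3)
  for (i in seq_len(n)) counts[g1[i] + 1, g2[i] + 1] <-
      counts[g1[i] + 1, g2[i] + 1] + 1

  p <- mean(g1) / 2 # alt frequency, locus 1
  q <- mean(g2) / 2
  h <- c(h11 = p * q, h10 = p * (1 - q), h01 = (1 - p) * q,
         h00 = (1 - p) * (1 - q))

  loglik_of <- function(h) {
    pr <- matrix(0, 3, 3) # P(genotype pair) from random union of haplotypes
    pr[3, 3] <- h["h11"]^2
    pr[3, 2] <- 2 * h["h11"] * h["h10"]
    pr[3, 1] <- h["h10"]^2
    pr[2, 3] <- 2 * h["h11"] * h["h01"]
    pr[2, 2] <- 2 * (h["h11"] * h["h00"] + h["h10"] * h["h01"])
    pr[2, 1] <- 2 * h["h10"] * h["h00"]
    pr[1, 3] <- h["h01"]^2
    pr[1, 2] <- 2 * h["h01"] * h["h00"]
    pr[1, 1] <- h["h00"]^2
    sum(counts[counts > 0] * log(pr[counts > 0]))
  }

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # expected haplotype counts; only counts[2,2] (double het) needs splitting
    coupling <- h[["h11"]] * h[["h00"]]
    repulsion <- h[["h10"]] * h[["h01"]]
    w <- if (coupling + repulsion > 0) coupling / (coupling + repulsion) else 0.5
    e11 <- 2 * counts[3, 3] + counts[3, 2] + counts[2, 3] + w * counts[2, 2]
    e10 <- 2 * counts[3, 1] + counts[3, 2] + counts[2, 1] + (1 - w) * counts[2, 2]
    e01 <- 2 * counts[1, 3] + counts[2, 3] + counts[1, 2] + (1 - w) * counts[2, 2]
    e00 <- 2 * counts[1, 1] + counts[2, 1] + counts[1, 2] + w * counts[2, 2]
    h_new <- c(h11 = e11, h10 = e10, h01 = e01, h00 = e00) / (2 * n)
    trace <- c(trace, loglik_of(h_new))
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter,
            " iterations; returning best estimate")
  ld <- d_prime_r2(h)
  structure(list(haplotypes = h, D = ld$D, Dprime = ld$Dprime, r2 = ld$r2,
                 iterations = it, loglik = trace[length(trace)],
                 loglik_trace = trace),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("ld_result: D' = %.3f, r2 = %.3f (D = %.4f, %d EM iterations)\n",
              x$Dprime, x$r2, x$D, x$iterations))
  invisible(x)
}

#' Lewontin's D' and r-squared from four haplotype frequencies
#'
#' `D = f11 - p q` with `p`, `q` the locus marginals;
#' `D' = |D| / Dmax` where `Dmax = min(p(1-q), (1-p)q)` if D > 0 and
#' `min(pq, (1-p)(1-q))` otherwise; `r2 = D^2 / (p(1-p)q(1-q))`. D' is 0 by
#' convention when D = 0. Both statistics are invariant to allele-label
#' swaps at either locus.
#'
#' @param hap_freqs numeric vector `(h11, h10, h01, h00)` summing to 1.
#' @return list with `D`, `Dprime`, `r2`.
#' @export
d_prime_r2 <- function(hap_freqs) {
  stopifnot(length(hap_freqs) == 4, all(hap_freqs >= -1e-12))
  if (abs(sum(hap_freqs) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1")
  h11 <- unname(hap_freqs[1]); h10 <- unname(hap_freqs[2])
  h01 <- unname(hap_freqs[3])
  p <- h11 + h10
  q <- h11 + h01
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1)
    stop("degenerate (fixed) locus: LD undefined")
  D <- h11 - p * q
  if (D == 0) {
    dprime <- 0
  } else {
    dmax <- if (D > 0) min(p * (1 - q), (1 - p) * q)
            else min(p * q, (1 - p) * (1 - q))
    dprime <- abs(D) / dmax
  }
  list(D = D, Dprime = dprime, r2 = D^2 / (p * (1 - p) * q * (1 - q)))
}
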