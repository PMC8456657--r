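#' Build a per-SNP allele-frequency table for several populations
#'
#' Raw (unsmoothed) sample alternate-allele frequencies and called-allele
#' counts per population on a shared SNP set, the input to the f-statistics.
#'
#' @param gms named list of [genotype_matrix()] objects on identical SNPs.
#' @return data frame with `chrom`, `pos`, then `freq_<pop>` and `n_<pop>`
#'   columns, of class `freq_table`.
#' @export
freq_table <- function(gms) {
  stopifnot(is.list(gms), length(gms) >= 1, !is.null(names(gms)))
  ref <- gms[[1]]$snps
  for (gm in gms) {
    if (!identical(gm$snps$pos, ref$pos) || !identical(gm$snps$chrom, ref$chrom))
      stop("all populations must share the same SNP set")
  }
  ft <- data.frame(chrom = ref$chrom, pos = ref$pos, stringsAsFactors = FALSE)
  for (nm in names(gms)) {
    g <- gms[[nm]]$geno
    cnt <- colSums(g, na.rm = TRUE)
    tot <- 2 * colSums(!is.na(g))
    ft[[paste0("freq_", nm)]] <- ifelse(tot > 0, cnt / tot, NA_real_)
    ft[[paste0("n_", nm)]] <- tot
  }
  class(ft) <- c("freq_table", "data.frame")
  ft
}

ft_cols <- function(ft, pop) {
  fc <- paste0("freq_", pop); nc <- paste0("n_", pop)
  if (!fc %in% names(ft)) stop("population not in frequency table: ", pop)
  list(f = ft[[fc]], n = ft[[nc]])
}

fstat_result <- function(stat, value, se, n_snps, n_blocks) {
  structure(list(stat = stat, value = value, se = se,
                 z = if (se > 0) value / se else NA_real_,
                 n_snps = n_snps, n_blocks = n_blocks),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s = %.6g  SE = %.3g  Z = %.2f  (%d SNPs, %d blocks)\n",
              x$stat, x$value, x$se, x$z, x$n_snps, x$n_blocks))
  invisible(x)
}

#' f3 admixture test
#'
#' Computes `f3(C; A, B) = mean over SNPs of (c - a)(c - b)`, minus (by
#' default) the finite-sample bias correction `c(1-c) / (n_C - 1)` -- the
#' unbiased-variance correction for the sampling noise of the target's
#' frequency estimate, as in the qp3Pop estimator. A significantly negative
#' f3 indicates that C descends from a mixture of populations related to A
#' and B. Standard error and Z score come from a weighted block jackknife
#' over contiguous SNP blocks.
#'
#' SNPs with a missing frequency (or, when correcting, fewer than 2 called
#' alleles in C) in any of the three populations are dropped; SNPs
#' monomorphic in all three contribute 0 and are retained.
#'
#' @param ft a [freq_table()].
#' @param target,source_a,source_b population names in `ft`.
#' @param block_size SNPs per jackknife block (default 500).
#' @param correction apply the finite-sample correction (default TRUE).
#' @return an `fstat_result` (value, SE, Z, SNP and block counts).
#' @export
f3 <- function(ft, target, source_a, source_b, block_size = 500,
               correction = TRUE) {
  cc <- ft_cols(ft, target); aa <- ft_cols(ft, source_a); bb <- ft_cols(ft, source_b)
  ok <- !is.na(cc$f) & !is.na(aa$f) & !is.na(bb$f)
  if (correction) ok <- ok & cc$n >= 2
  c_ <- cc$f[ok]; a_ <- aa$f[ok]; b_ <- bb$f[ok]
  terms <- (c_ - a_) * (c_ - b_)
  if (correction) terms <- terms - c_ * (1 - c_) / (cc$n[ok] - 1)
  jk <- block_jackknife(terms, block_size)
  fstat_result("f3", jk$estimate, jk$se, length(terms), jk$n_blocks)
}

#' f4 statistic
#'
#' `f4(A, B; C, D) = mean over SNPs of (a - b)(c - d)`, with block-jackknife
#' SE and Z. Antisymmetric under swapping within either pair.
#'
#' @param ft a [freq_table()].
#' @param a,b,c,d population names in `ft`.
#' @param block_size SNPs per jackknife block.
#' @return an `fstat_result`.
#' @export
f4 <- function(ft, a, b, c, d, block_size = 500) {
  A <- ft_cols(ft, a); B <- ft_cols(ft, b); C <- ft_cols(ft, c); D <- ft_cols(ft, d)
  ok <- !is.na(A$f) & !is.na(B$f) & !is.na(C$f) & !is.na(D$f)
  terms <- (A$f[ok] - B$f[ok]) * (C$f[ok] - D$f[ok])
  jk <- block_jackknife(terms, block_size)
  fstat_result("f4", jk$estimate, jk$se, length(terms), jk$n_blocks)
}

#' f4-ratio estimate of an admixture proportion
#'
#' `alpha = f4(A, O; X, B) / f4(A, O; A2, B)`: with an outgroup O, a target
#' X admixed between sources related to A and B, and A2 a second proxy for
#' the A-side source, the ratio estimates the A-ancestry proportion of X.
#' The SE is obtained by jackknifing the ratio itself over contiguous SNP
#' blocks (delete one block, recompute both f4 means and their ratio).
#'
#' @param ft a [freq_table()].
#' @param numerator character vector of 4 population names (A, O, X, B).
#' @param denominator character vector of 4 population names (A, O, A2, B).
#' @param block_size SNPs per jackknife block.
#' @return an `fstat_result` whose `value` is the admixture proportion.
#' @export
f4_ratio <- function(ft, numerator, denominator, block_size = 500) {
  stopifnot(length(numerator) == 4, length(denominator) == 4)
  tn <- lapply(numerator, function(p) ft_cols(ft, p))
  td <- lapply(denominator, function(p) ft_cols(ft, p))
  ok <- Reduce(`&`, lapply(c(tn, td), function(x) !is.na(x$f)))
  num <- (tn[[1]]$f[ok] - tn[[2]]$f[ok]) * (tn[[3]]$f[ok] - tn[[4]]$f[ok])
  den <- (td[[1]]$f[ok] - td[[2]]$f[ok]) * (td[[3]]$f[ok] - td[[4]]$f[ok])
  if (mean(den) == 0) stop("denominator f4 is zero")
  jk_den <- block_jackknife(den, block_size)
  if (is.na(jk_den$se) || jk_den$se == 0 || abs(jk_den$estimate / jk_den$se) < 3)
    warning("denominator f4 is not significantly non-zero (|Z| < 3); ",
            "the ratio may be unstable")
  jk <- block_jackknife_ratio(num, den, block_size)
  fstat_result("f4_ratio", jk$estimate, jk$se, length(num), jk$n_blocks)
}

block_bounds <- function(n, block_size) {
  if (block_size >= n)
    stop("block_size (", block_size, ") must be smaller than the SNP count (",
         n, ")")
  starts <- seq(1, n, by = block_size)
  ends <- pmin(starts + block_size - 1, n)
  if (length(starts) < 2) stop("need at least 2 jackknife blocks")
  data.frame(start = starts, end = ends)
}

# Weighted delete-one-block jackknife (Busing, Meijer & van der Leeden 1999),
# the estimator used with f statistics: blocks may have unequal SNP counts.
busing_jackknife <- function(theta_hat, theta_j, m_j) {
  n <- sum(m_j)
  g <- length(theta_j)
  h <- n / m_j
  theta_J <- g * theta_hat - sum((1 - m_j / n) * theta_j)
  tau <- h * theta_hat - (h - 1) * theta_j
  var_j <- mean((tau - theta_J)^2 / (h - 1))
  list(estimate = theta_hat, se = sqrt(var_j), n_blocks = g)
}

#' Weighted block jackknife of a per-SNP mean
#'
#' Delete-one-block jackknife over contiguous SNP blocks, weighting blocks by
#' their SNP counts. Robust to linkage disequilibrium as long as the block
#' size exceeds the LD scale.
#'
#' @param per_snp_terms numeric vector of per-SNP contributions.
#' @param block_size SNPs per block; the last block may be smaller. Must
#'   leave at least 2 blocks.
#' @return list with `estimate` (the plain mean), `se`, `n_blocks`.
#' @export
block_jackknife <- function(per_snp_terms, block_size = 500) {
  n <- length(per_snp_terms)
  bl <- block_bounds(n, block_size)
  tot <- sum(per_snp_terms)
  theta_hat <- tot / n
  m_j <- bl$end - bl$start + 1
  block_sums <- vapply(seq_len(nrow(bl)),
                       function(j) sum(per_snp_terms[bl$start[j]:bl$end[j]]),
                       numeric(1))
  theta_j <- (tot - block_sums) / (n - m_j)
  busing_jackknife(theta_hat, theta_j, m_j)
}

block_jackknife_ratio <- function(num_terms, den_terms, block_size = 500) {
  n <- length(num_terms)
  bl <- block_bounds(n, block_size)
  tot_n <- sum(num_terms); tot_d <- sum(den_terms)
  theta_hat <- tot_n / tot_d
  m_j <- bl$end - bl$start + 1
  bs_n <- vapply(seq_len(nrow(bl)),
                 function(j) sum(num_terms[bl$start[j]:bl$end[j]]), numeric(1))
  bs_d <- vapply(seq_len(nrow(bl)),
                 function(j) sum(den_terms[bl$start[j]:bl$end[j]]), numeric(1))
  theta_j <- (tot_n - bs_n) / (tot_d - bs_d)
  busing_jackknife(theta_hat, theta_j, m_j)
}
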