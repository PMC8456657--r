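#' Sample one haplotype's ancestry tracts after pulse admixture
#'
#' Under a single-pulse admixture g generations ago, ancestry along a
#' chromosome is approximated by a Markov process: ancestry-switch
#' opportunities arrive as a Poisson process with rate g per Morgan and each
#' redraws the ancestry from the stationary distribution
#' (alpha_P, 1 - alpha_P). Complete P tracts therefore have mean length
#' 1 / (g * (1 - alpha_P)) Morgans, the standard admixture-tract expectation.
#'
#' @param length_morgans tract sampling window in Morgans.
#' @param g generations since admixture.
#' @param alpha_P stationary P-ancestry proportion.
#' @return data frame with `start`, `end` (Morgans) and `ancestry`
#'   (1 = P, 0 = A) per tract.
#' @export
simulate_ancestry_tracts <- function(length_morgans, g, alpha_P) {
  stopifnot(length_morgans > 0, g >= 1, alpha_P >= 0, alpha_P <= 1)
  k <- stats::rpois(1, g * length_morgans)
  bp <- sort(stats::runif(k, 0, length_morgans))
  states <- stats::rbinom(k + 1, 1, alpha_P)
  edges <- c(0, bp, length_morgans)
  tr <- data.frame(start = edges[-length(edges)], end = edges[-1],
                   ancestry = states)
  # merge consecutive tracts with equal ancestry (a redraw may keep the state)
  grp <- cumsum(c(1L, diff(tr$ancestry) != 0))
  data.frame(start = tapply(tr$start, grp, min),
             end = tapply(tr$end, grp, max),
             ancestry = tapply(tr$ancestry, grp, unique),
             row.names = NULL)
}

seg_offset <- function(config, seg) {
  ((seg - 1L) %% config$segments_per_chromosome) * config$segment_stride
}

seg_chrom <- function(config, seg) {
  if (!length(seg)) return(character(0)) # paste0 would promote to length 1
  paste0("chr", (seg - 1L) %/% config$segments_per_chromosome + 1L)
}

#' Simulate a neutral two-source admixture dataset
#'
#' Generates genotype matrices for the two source populations, the admixed
#' population (and optionally an outgroup) plus true per-haplotype local
#' ancestry, under the demography in `config`. The generator is
#' frequency-based: for each segment, candidate site frequencies in the
#' ancestral population are drawn from the neutral site-frequency spectrum
#' (density proportional to 1/x), drifted forward along each branch by exact
#' per-generation Wright-Fisher binomial sampling, and sampled as
#' Hardy-Weinberg genotypes. Admixed haplotypes are ancestry-tract mosaics
#' (see [simulate_ancestry_tracts()]) copying alleles from the source
#' frequencies at admixture time. Sites monomorphic in the pooled sample are
#' dropped, so every returned SNP is polymorphic overall.
#'
#' @param config a [demography_config()].
#' @param seed optional integer seed (`set.seed` is called once; all stages
#'   then share R's RNG stream).
#' @return an object of class `sim_dataset`: genotype matrices `P`,
#'   `admixed`, `A` (and `O` if an outgroup was requested), `true_ancestry`
#'   (haplotypes x SNPs, 1 = P), `segment` (segment index per SNP), and
#'   `freqs` (per-SNP source population frequencies at admixture time and at
#'   sampling time, used by [inject_selected_locus()]).
#' @export
simulate_neutral <- function(config, seed = NULL) {
  stopifnot(inherits(config, "demography_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  sc <- cfg$sample_chromosomes
  n_pool <- sum(sc) + if (cfg$include_outgroup) cfg$outgroup_chromosomes else 0
  # candidate site count: Watterson expectation for the pooled sample, with a
  # 1.6x margin because drift over t_split fixes a large share of the
  # (mostly rare) SFS draws before sampling
  a_n <- sum(1 / seq_len(n_pool - 1))
  theta_seg <- 4 * cfg$N * cfg$mu * cfg$segment_length
  s_seg <- stats::rpois(cfg$n_segments, theta_seg * a_n * 1.6)
  s_seg <- pmin(s_seg, cfg$segment_length)
  total <- sum(s_seg)

  seg_id <- rep(seq_len(cfg$n_segments), s_seg)
  pos_local <- unlist(lapply(s_seg, function(s) {
    sort(sample.int(cfg$segment_length, s))
  }), use.names = FALSE)
  if (is.null(pos_local)) pos_local <- integer(0)

  # ancestral frequencies from the neutral SFS, density ~ 1/x, truncated at
  # the single-copy frequency
  xmin <- 1 / (2 * cfg$N)
  p_anc <- xmin * ((1 - xmin) / xmin)^stats::runif(total)

  if (cfg$include_outgroup) {
    p_O_now <- wf_drift_cpp(p_anc, cfg$t_outgroup, cfg$N)
    p_node <- wf_drift_cpp(p_anc, cfg$t_outgroup - cfg$t_split, cfg$N)
  } else {
    p_node <- p_anc
  }
  p_P_adm <- wf_drift_cpp(p_node, cfg$t_split - cfg$g, cfg$N)
  p_A_adm <- wf_drift_cpp(p_node, cfg$t_split - cfg$g, cfg$N)
  p_P_now <- wf_drift_cpp(p_P_adm, cfg$g, cfg$N)
  p_A_now <- wf_drift_cpp(p_A_adm, cfg$g, cfg$N)

  hw_geno <- function(n_ind, p) {
    matrix(stats::rbinom(n_ind * length(p), 2, rep(p, each = n_ind)),
           nrow = n_ind)
  }
  geno_P <- hw_geno(sc[["P"]] / 2, p_P_now)
  geno_A <- hw_geno(sc[["A"]] / 2, p_A_now)
  if (cfg$include_outgroup) geno_O <- hw_geno(cfg$outgroup_chromosomes / 2, p_O_now)

  # admixed haplotypes: ancestry tracts per segment, alleles copied from the
  # admixture-time source frequencies
  n_hap <- sc[["admixed"]]
  anc <- matrix(0L, n_hap, total)
  hapA <- matrix(0L, n_hap, total)
  lambda <- cfg$g * cfg$rec * cfg$segment_length
  seg_starts <- c(0L, cumsum(s_seg))
  for (seg in seq_len(cfg$n_segments)) {
    if (s_seg[seg] == 0) next
    idx <- (seg_starts[seg] + 1L):seg_starts[seg + 1L]
    pl <- pos_local[idx]
    for (h in seq_len(n_hap)) {
      k <- stats::rpois(1, lambda)
      if (k == 0) {
        anc[h, idx] <- stats::rbinom(1, 1, cfg$alpha_P)
      } else {
        bp <- sort(stats::runif(k, 0, cfg$segment_length))
        states <- stats::rbinom(k + 1, 1, cfg$alpha_P)
        anc[h, idx] <- states[findInterval(pl, bp) + 1L]
      }
    }
    prob <- matrix(rep(p_A_adm[idx], each = n_hap), n_hap)
    sel <- anc[, idx, drop = FALSE] == 1L
    if (any(sel)) {
      col_of <- (which(sel) - 1L) %/% n_hap + 1L
      prob[sel] <- p_P_adm[idx][col_of]
    }
    hapA[, idx] <- stats::rbinom(length(prob), 1, prob)
  }
  odd <- seq(1, n_hap, by = 2)
  geno_adm <- hapA[odd, , drop = FALSE] + hapA[odd + 1L, , drop = FALSE]

  # pooled-sample polymorphism filter
  cnt <- colSums(geno_P) + colSums(geno_A) + colSums(geno_adm)
  tot_alleles <- 2 * (nrow(geno_P) + nrow(geno_A) + nrow(geno_adm))
  if (cfg$include_outgroup) {
    cnt <- cnt + colSums(geno_O)
    tot_alleles <- tot_alleles + 2 * nrow(geno_O)
  }
  keep <- which(cnt > 0 & cnt < tot_alleles)

  snps <- data.frame(
    chrom = seg_chrom(cfg, seg_id[keep]),
    pos = as.integer(seg_offset(cfg, seg_id[keep]) + pos_local[keep]),
    ref = rep("A", length(keep)), alt = rep("G", length(keep)),
    stringsAsFactors = FALSE
  )
  mk <- function(geno, prefix) {
    genotype_matrix(sprintf("%s_%02d", prefix, seq_len(nrow(geno))), snps,
                    geno[, keep, drop = FALSE])
  }
  ds <- list(
    P = mk(geno_P, "P"), admixed = mk(geno_adm, "ADM"), A = mk(geno_A, "A"),
    true_ancestry = anc[, keep, drop = FALSE],
    segment = seg_id[keep],
    freqs = list(P_adm = p_P_adm[keep], A_adm = p_A_adm[keep],
                 P_now = p_P_now[keep], A_now = p_A_now[keep]),
    config = cfg, seed = seed
  )
  if (cfg$include_outgroup) {
    ds$O <- mk(geno_O, "O")
    ds$freqs$O_now <- p_O_now[keep]
  }
  rownames(ds$true_ancestry) <-
    sprintf("ADM_%02d_h%d", rep(seq_len(n_hap / 2), each = 2), 1:2)
  structure(ds, class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", n_snps(x$admixed), "SNPs,",
      x$config$n_segments, "segments\n")
  cat("  populations:",
      paste(intersect(c("P", "admixed", "A", "O"), names(x)), collapse = ", "),
      "\n")
  if (!is.null(x$selected))
    cat(sprintf("  selected locus: segment %d, s = %.4g\n",
                x$selected$spec$segment, x$selected$spec$s))
  invisible(x)
}

#' Subset a simulated dataset by SNP index
#'
#' Keeps the SNP columns `idx` (sorted ascending) consistently across the
#' genotype matrices, the true-ancestry matrix and the stored frequencies.
#'
#' @param ds a `sim_dataset`.
#' @param idx integer SNP indices.
#' @return a `sim_dataset`.
#' @export
subset_sim_dataset <- function(ds, idx) {
  idx <- sort(unique(as.integer(idx)))
  for (pop in intersect(c("P", "admixed", "A", "O"), names(ds)))
    ds[[pop]] <- subset_snps(ds[[pop]], idx)
  ds$true_ancestry <- ds$true_ancestry[, idx, drop = FALSE]
  ds$segment <- ds$segment[idx]
  ds$freqs <- lapply(ds$freqs, function(f) f[idx])
  ds
}

#' Ascertainment-thin SNPs to match a minor-allele-frequency profile
#'
#' Emulates genotyping-array ascertainment: SNPs are binned by pooled-sample
#' minor allele frequency into equal-width bins spanning (0, 0.5], a per-bin
#' quota is computed from `maf_reference` by largest-remainder rounding of
#' the proportional allocation, and SNPs are drawn at random within bins.
#' If a bin holds fewer SNPs than its quota, all of its SNPs are kept and a
#' warning is logged (quotas are not redistributed).
#'
#' @param ds a `sim_dataset`.
#' @param target_count number of SNPs to retain.
#' @param maf_reference non-negative weights per MAF bin; the default is a
#'   uniform 10-bin (width 0.05) profile, a coarse description of the flat
#'   MAF spectrum typical of array SNPs.
#' @param seed optional integer seed.
#' @return the thinned `sim_dataset`.
#' @export
ascertain_snps <- function(ds, target_count, maf_reference = rep(0.1, 10),
                           seed = NULL) {
  stopifnot(inherits(ds, "sim_dataset"), target_count >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (length(maf_reference) < 1 || all(maf_reference == 0) ||
      any(maf_reference < 0))
    stop("maf_reference must contain at least one positive bin mass")
  S <- n_snps(ds$admixed)
  if (target_count > S)
    stop("target_count (", target_count, ") exceeds available SNPs (", S, ")")

  pops <- intersect(c("P", "admixed", "A", "O"), names(ds))
  cnt <- Reduce(`+`, lapply(pops, function(p) colSums(ds[[p]]$geno, na.rm = TRUE)))
  tot <- Reduce(`+`, lapply(pops, function(p) 2 * colSums(!is.na(ds[[p]]$geno))))
  f <- cnt / tot
  maf <- pmin(f, 1 - f)
  nb <- length(maf_reference)
  width <- 0.5 / nb
  bin <- pmin(pmax(ceiling(maf / width), 1L), nb)

  w <- maf_reference / sum(maf_reference)
  quota <- largest_remainder(target_count * w)
  keep <- integer(0)
  for (b in seq_len(nb)) {
    in_bin <- which(bin == b)
    if (quota[b] > length(in_bin)) {
      warning(sprintf("MAF bin %d exhausted: wanted %d SNPs, found %d",
                      b, quota[b], length(in_bin)))
      keep <- c(keep, in_bin)
    } else if (quota[b] > 0) {
      keep <- c(keep, sample(in_bin, quota[b]))
    }
  }
  subset_sim_dataset(ds, keep)
}

# integer allocation by largest-remainder rounding; ties broken by bin order
largest_remainder <- function(q) {
  base <- floor(q)
  rem <- round(sum(q)) - sum(base)
  if (rem > 0) {
    extra <- order(q - base, seq_along(q), decreasing = c(TRUE, FALSE),
                   method = "radix")[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Inject a post-admixture selected locus into a simulated dataset
#'
#' Re-simulates the admixed population at one segment forward in time for g
#' generations with additive selection favouring the P-derived allele at a
#' focal SNP. To emulate selection on a variant introduced by the P-side
#' ancestors, the focal SNP is the most P-diagnostic SNP (largest
#' admixture-time frequency difference between the sources) within 250 kb of
#' `spec$position`, widening to the whole segment if that window is empty;
#' the favoured allele is the one more frequent in source P.
#' The founding population of 2N haplotypes is drawn from the admixture
#' pulse; recombination then builds ancestry tracts, so linked P ancestry
#' around the locus rises with the selected allele. Sampled admixed
#' genotypes and true ancestry at the segment are replaced.
#'
#' @param ds a `sim_dataset` from [simulate_neutral()].
#' @param spec a [selected_locus_spec()].
#' @param seed optional integer seed.
#' @return the modified `sim_dataset`, with a `selected` element recording
#'   the focal SNP index, the realised founder frequency `p0` and the final
#'   favoured-allele frequency.
#' @export
inject_selected_locus <- function(ds, spec, seed = NULL) {
  stopifnot(inherits(ds, "sim_dataset"), inherits(spec, "selected_locus_spec"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- ds$config
  if (spec$segment > cfg$n_segments) stop("segment index out of range")
  idx <- which(ds$segment == spec$segment)
  if (!length(idx)) stop("no SNPs in segment ", spec$segment)
  pos_loc <- ds$admixed$snps$pos[idx] - seg_offset(cfg, spec$segment)
  fP <- ds$freqs$P_adm[idx]
  fA <- ds$freqs$A_adm[idx]
  near <- which(abs(pos_loc - spec$position) <= 250000)
  if (!length(near)) near <- seq_along(idx)
  focal <- near[which.max(abs(fP - fA)[near])]
  favored <- if (fP[focal] >= fA[focal]) 1L else 0L

  H <- 2 * cfg$N
  S <- length(idx)
  anc_f <- matrix(rep(stats::rbinom(H, 1, cfg$alpha_P), S), H, S)
  prob <- ifelse(anc_f == 1L, matrix(rep(fP, each = H), H),
                 matrix(rep(fA, each = H), H))
  alle_f <- matrix(stats::rbinom(H * S, 1, prob), H, S)
  p0 <- mean(alle_f[, focal] == favored)

  res <- forward_selection_cpp(alle_f, anc_f, as.numeric(pos_loc), cfg$rec,
                               cfg$g, focal - 1L, favored, spec$s)
  n_hap <- cfg$sample_chromosomes[["admixed"]]
  pick <- sample(H, n_hap)
  hapA <- res$alleles[pick, , drop = FALSE]
  hapC <- res$ancestry[pick, , drop = FALSE]
  odd <- seq(1, n_hap, by = 2)
  ds$admixed$geno[, idx] <- hapA[odd, , drop = FALSE] + hapA[odd + 1L, , drop = FALSE]
  ds$true_ancestry[, idx] <- hapC
  ds$selected <- list(spec = spec, snp_index = idx[focal], p0 = p0,
                      final_freq = mean(res$alleles[, focal] == favored))
  ds
}

#' True ancestry dosage from recorded haplotype labels
#'
#' Collapses the per-haplotype true ancestry labels of a simulated dataset to
#' per-individual P-copy counts (0, 1 or 2 at each SNP) -- the ground truth
#' against which inferred dosages are evaluated.
#'
#' @param ds a `sim_dataset`.
#' @return an `ancestry_dosage` object (see [infer_dosage()]).
#' @export
true_dosage <- function(ds) {
  stopifnot(inherits(ds, "sim_dataset"))
  n_hap <- nrow(ds$true_ancestry)
  odd <- seq(1, n_hap, by = 2)
  dosage <- ds$true_ancestry[odd, , drop = FALSE] +
    ds$true_ancestry[odd + 1L, , drop = FALSE]
  rownames(dosage) <- ds$admixed$samples
  ancestry_dosage(dosage, ds$admixed$snps)
}
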