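#' Genome-wide summary of an ancestry track
#'
#' Mean and population-denominator SD of the per-SNP mean P-ancestry
#' proportion, and excess thresholds at mean + k SD for k = 2, 4, 5. With a
#' genome-wide mean of 24.6% and SD of 8.63% the 5 SD threshold is 67.75%,
#' printed as "> 67.8%".
#'
#' @param track numeric vector of per-SNP mean ancestry proportions
#'   (at least 2 values).
#' @return an object of class `scan_summary` with `mean`, `sd` and a named
#'   `thresholds` vector (`k2`, `k4`, `k5`).
#' @export
scan_stats <- function(track) {
  if (length(track) < 2) stop("track must contain at least 2 SNPs")
  m <- mean(track)
  s <- sqrt(mean((track - m)^2)) # population SD (n denominator)
  structure(list(mean = m, sd = s,
                 thresholds = c(k2 = m + 2 * s, k4 = m + 4 * s, k5 = m + 5 * s),
                 n_snps = length(track)),
            class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat(sprintf("scan_summary: mean %.3f, SD %.4f over %d SNPs\n",
              x$mean, x$sd, x$n_snps))
  cat(sprintf("  thresholds: 2SD %.3f | 4SD %.3f | 5SD %.3f\n",
              x$thresholds["k2"], x$thresholds["k4"], x$thresholds["k5"]))
  invisible(x)
}

#' Call ancestry-excess regions from a track
#'
#' Identifies maximal runs of consecutive SNPs with track value strictly
#' greater than `threshold`, per chromosome. Runs on the same chromosome are
#' merged into one region when they are separated by less than `merge_bp`
#' AND by fewer than `merge_snps` below-threshold SNPs; surviving runs are
#' reported as independent regions. Regions never span chromosomes.
#'
#' @param track per-SNP mean ancestry proportions.
#' @param positions physical positions (1-based bp), same length as `track`.
#' @param chromosomes chromosome label per SNP.
#' @param threshold proportion in [0, 1]; SNPs must exceed it strictly.
#' @param merge_bp,merge_snps merge rule for nearby runs (defaults 1 Mb / 5
#'   SNPs).
#' @return data frame with columns `chrom`, `start`, `end` (positions of the
#'   first/last above-threshold SNP), `n_snps` (above-threshold SNPs in the
#'   region), `max_prop`, `mean_prop`.
#' @export
call_regions <- function(track, positions, chromosomes, threshold,
                         merge_bp = 1e6, merge_snps = 5) {
  stopifnot(length(track) == length(positions),
            length(track) == length(chromosomes),
            threshold >= 0, threshold <= 1)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      max_prop = numeric(0), mean_prop = numeric(0))
  out <- list()
  for (ch in unique(chromosomes)) {
    sel <- which(chromosomes == ch)
    tr <- track[sel]
    pos <- positions[sel]
    above <- tr > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # merge nearby runs
    if (nrow(runs) > 1) {
      grp <- 1L
      groups <- integer(nrow(runs))
      groups[1] <- grp
      for (i in 2:nrow(runs)) {
        gap_bp <- pos[runs$start[i]] - pos[runs$end[i - 1]]
        gap_snps <- runs$start[i] - runs$end[i - 1] - 1L
        if (gap_bp < merge_bp && gap_snps < merge_snps) {
          groups[i] <- grp
        } else {
          grp <- grp + 1L
          groups[i] <- grp
        }
      }
    } else groups <- 1L
    for (gr in unique(groups)) {
      rs <- runs[groups == gr, , drop = FALSE]
      i0 <- min(rs$start); i1 <- max(rs$end)
      idx_above <- unlist(Map(seq, rs$start, rs$end))
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = pos[i0], end = pos[i1],
        n_snps = length(idx_above),
        max_prop = max(tr[idx_above]), mean_prop = mean(tr[idx_above])
      )
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Estimate the family-wise error rate of the ancestry scan by simulation
#'
#' Runs `n_runs` independent neutral pipelines -- simulate,
#' ascertainment-thin, infer dosage with the simulated source samples as
#' reference panels, and call regions at that
#' run's own mean + k SD threshold -- and reports the fraction of runs with
#' at least one called region. With the study-scale demography (3000
#' segments) and k = 5 this estimates the probability of any false region
#' per neutral genome.
#'
#' @param n_runs number of neutral simulation runs.
#' @param config a [demography_config()].
#' @param seed integer seed; run i uses `seed + i - 1`.
#' @param target_count SNPs retained by ascertainment; defaults to the
#'   study-scale 162358 scaled by `n_segments / 3000`.
#' @param maf_reference MAF bin weights passed to [ascertain_snps()].
#' @param k threshold multiplier (regions exceed mean + k SD).
#' @param eps HMM per-allele error rate.
#' @return list with `fwer`, per-run `region_counts`, and `n_runs`.
#' @export
estimate_fwer <- function(n_runs, config, seed = 1, target_count = NULL,
                          maf_reference = rep(0.1, 10), k = 5, eps = 0.005) {
  stopifnot(n_runs >= 1)
  if (is.null(target_count))
    target_count <- round(162358 * config$n_segments / 3000)
  counts <- integer(n_runs)
  for (i in seq_len(n_runs)) {
    counts[i] <- tryCatch(
      fwer_one_run(config, seed + i - 1, target_count, maf_reference, k, eps),
      error = function(e) stop("neutral run ", i, " failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  list(fwer = mean(counts >= 1), region_counts = counts, n_runs = n_runs)
}

fwer_one_run <- function(config, seed, target_count, maf_reference, k, eps) {
  ds <- simulate_neutral(config, seed = seed)
  ds <- ascertain_snps(ds, min(target_count, n_snps(ds$admixed)),
                       maf_reference)
  dm <- infer_dosage(ds$admixed, estimate_source_freqs(ds$P),
                     estimate_source_freqs(ds$A),
                     hmm_params(g = config$g, rec = config$rec, eps = eps))
  track <- mean_ancestry_track(dm)
  st <- scan_stats(track)
  nrow(call_regions(track, ds$admixed$snps$pos, ds$admixed$snps$chrom,
                    st$mean + k * st$sd))
}

#' False discovery rate from a family-wise error rate
#'
#' Under the reasoning that at most one false region is expected per
#' significant genome, the FDR of an observed scan is the simulated FWER
#' divided by the number of regions observed in the real data:
#' `fdr_from_fwer(0.09, 2)` gives 0.045.
#'
#' @param fwer simulated family-wise error rate in [0, 1].
#' @param n_observed_regions number of regions called in the observed scan
#'   (must be at least 1).
#' @return the FDR estimate.
#' @export
fdr_from_fwer <- function(fwer, n_observed_regions) {
  stopifnot(fwer >= 0, fwer <= 1)
  if (n_observed_regions < 1)
    stop("FDR is undefined with zero observed regions")
  fwer / n_observed_regions
}

#' Remove SNPs monomorphic in any population
#'
#' A SNP is kept only if both alleles are observed in every population's
#' sample (the usual requirement before local ancestry inference).
#'
#' @param ds a `sim_dataset`.
#' @param pops populations to require polymorphism in (default P, admixed, A).
#' @return the filtered `sim_dataset`.
#' @export
filter_polymorphic <- function(ds, pops = c("P", "admixed", "A")) {
  stopifnot(inherits(ds, "sim_dataset"))
  keep <- rep(TRUE, n_snps(ds$admixed))
  for (p in pops) {
    g <- ds[[p]]$geno
    cnt <- colSums(g, na.rm = TRUE)
    tot <- 2 * colSums(!is.na(g))
    keep <- keep & cnt > 0 & cnt < tot
  }
  subset_sim_dataset(ds, which(keep))
}
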