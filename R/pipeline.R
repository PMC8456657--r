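#' Run the full admixture-enabled-selection analysis
#'
#' Orchestrates the end-to-end pipeline from a single configuration:
#' obtain the three genotype matrices (simulated from a demography, or read
#' from files), drop SNPs monomorphic in any population, infer ancestry
#' dosage with the two source samples as reference panels, compute the
#' genome-wide scan summary, call ancestry-excess regions at mean + k SD,
#' and (optionally) calibrate the threshold by neutral simulation runs
#' (FWER, and FDR when regions were observed). Deterministic given `seed`.
#'
#' The configuration is a list (or a path to a JSON file with the same
#' structure) with either
#' \describe{
#'   \item{simulate}{list of [demography_config()] arguments, plus optional
#'     `target_count` / `maf_reference` for ascertainment and an optional
#'     `selected = list(segment, position, s)` locus to inject;}
#'   \item{inputs}{list with file paths `admixed`, `ref_p`, `ref_a` and
#'     optional `format`.}
#' }
#' plus optional top-level `k` (threshold multiplier, default 5),
#' `generations` (HMM g, default 100), `eps`, `n_null_runs` (default 0),
#' `exclude_samples` (labels dropped from the admixed panel, in lieu of
#' relatedness pruning) and `polymorphic_filter` (drop SNPs monomorphic in
#' any population before inference; defaults to TRUE for file inputs, the
#' usual real-data QC, and FALSE for simulated inputs, where at N = 1000 it
#' would delete the diagnostic fixed differences between the sources).
#'
#' @param config list or JSON file path.
#' @param seed integer seed for all randomness.
#' @param out_dir if non-NULL, artifacts are written there: `dosage.tsv`,
#'   `regions.tsv`, `report.json`, `report.txt`.
#' @return an object of class `pipeline_report`.
#' @export
run_pipeline <- function(config, seed = 1, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  set.seed(seed)
  k <- config$k %||% 5
  g_hmm <- config$generations %||% 100
  eps <- config$eps %||% 0.005

  if (!is.null(config$simulate)) {
    dem_args <- config$simulate
    dem_args$target_count <- NULL; dem_args$maf_reference <- NULL
    dem_args$selected <- NULL
    if (!is.null(dem_args$sample_chromosomes))
      dem_args$sample_chromosomes <- unlist(dem_args$sample_chromosomes)
    dem <- do.call(demography_config, dem_args)
    ds <- simulate_neutral(dem)
    if (!is.null(config$simulate$selected)) {
      sl <- config$simulate$selected
      ds <- inject_selected_locus(ds, selected_locus_spec(sl$segment,
                                                          sl$position, sl$s))
    }
    # the per-population polymorphism filter is real-data QC; at N = 1000 it
    # deletes the diagnostic fixed differences, so it defaults off for
    # simulated inputs (see the methods vignette)
    if (isTRUE(config$polymorphic_filter)) ds <- filter_polymorphic(ds)
    tc <- config$simulate$target_count %||%
      round(162358 * dem$n_segments / 3000)
    mr <- config$simulate$maf_reference %||% rep(0.1, 10)
    ds <- ascertain_snps(ds, min(tc, n_snps(ds$admixed)), mr)
    gm_adm <- ds$admixed; gm_p <- ds$P; gm_a <- ds$A
  } else if (!is.null(config$inputs)) {
    fmt <- config$inputs$format %||% "tsv"
    gm_adm <- read_genotypes(config$inputs$admixed, fmt)
    gm_p <- read_genotypes(config$inputs$ref_p, fmt)
    gm_a <- read_genotypes(config$inputs$ref_a, fmt)
    if (config$polymorphic_filter %||% TRUE) {
      poly <- function(gm) {
        cnt <- colSums(gm$geno, na.rm = TRUE)
        tot <- 2 * colSums(!is.na(gm$geno))
        cnt > 0 & cnt < tot
      }
      keep <- which(poly(gm_adm) & poly(gm_p) & poly(gm_a))
      gm_adm <- subset_snps(gm_adm, keep)
      gm_p <- subset_snps(gm_p, keep)
      gm_a <- subset_snps(gm_a, keep)
    }
    ds <- NULL
  } else stop("config must provide either $simulate or $inputs")

  if (!is.null(config$exclude_samples)) {
    keep_s <- !(gm_adm$samples %in% config$exclude_samples)
    gm_adm <- genotype_matrix(gm_adm$samples[keep_s], gm_adm$snps,
                              gm_adm$geno[keep_s, , drop = FALSE])
  }

  dm <- infer_dosage(gm_adm, estimate_source_freqs(gm_p),
                     estimate_source_freqs(gm_a),
                     hmm_params(g = g_hmm, eps = eps))
  track <- mean_ancestry_track(dm)
  st <- scan_stats(track)
  threshold <- st$mean + k * st$sd
  regions <- call_regions(track, gm_adm$snps$pos, gm_adm$snps$chrom, threshold)

  fwer <- NULL
  fdr <- NULL
  n_null <- config$n_null_runs %||% 0
  if (n_null > 0) {
    if (is.null(config$simulate))
      stop("null calibration requires a simulation configuration")
    fw <- estimate_fwer(n_null, dem, seed = seed + 1000, k = k, eps = eps)
    fwer <- fw$fwer
    if (nrow(regions) >= 1) fdr <- fdr_from_fwer(fwer, nrow(regions))
  }

  report <- structure(list(
    summary = st, threshold = threshold, k = k, regions = regions,
    fwer = fwer, fdr = fdr, n_null_runs = n_null,
    provenance = list(seed = seed, package_version =
                        as.character(utils::packageVersion("admixsel")),
                      config = config)
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    dos <- data.frame(chrom = gm_adm$snps$chrom, pos = gm_adm$snps$pos,
                      t(dm$dosage), mean_prop = track, check.names = FALSE)
    utils::write.table(dos, file.path(out_dir, "dosage.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(regions, file.path(out_dir, "regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
  }
  report
}

report_to_list <- function(report) {
  list(mean = report$summary$mean, sd = report$summary$sd,
       thresholds = as.list(report$summary$thresholds),
       k = report$k, threshold = report$threshold,
       n_snps = report$summary$n_snps,
       regions = report$regions,
       fwer = report$fwer, fdr = report$fdr,
       n_null_runs = report$n_null_runs,
       provenance = report$provenance)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== admixture-enabled selection scan ==\n")
  print(x$summary)
  cat(sprintf("  scan threshold (mean + %g SD): %.4f\n", x$k, x$threshold))
  if (nrow(x$regions) == 0) {
    cat("  no ancestry-excess regions\n")
  } else {
    cat("  regions:\n")
    print(x$regions, row.names = FALSE)
  }
  if (!is.null(x$fwer))
    cat(sprintf("  FWER over %d neutral runs: %.3f\n", x$n_null_runs, x$fwer))
  if (!is.null(x$fdr)) cat(sprintf("  FDR: %.4f\n", x$fdr))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
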