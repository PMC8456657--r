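#' Unphased diploid genotype matrix for one population
#'
#' Container for unphased genotypes: per-sample alternate-allele counts
#' (0, 1, 2 or `NA` for missing) together with per-SNP metadata. Positions
#' are 1-based physical coordinates and must be strictly increasing within
#' each chromosome.
#'
#' @param samples character vector of sample labels.
#' @param snps data frame with columns `chrom`, `pos`, `ref`, `alt`; one row
#'   per SNP.
#' @param geno integer matrix, samples in rows and SNPs in columns; values in
#'   `{0, 1, 2, NA}`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, snps, geno) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  rownames(snps) <- NULL
  gm <- structure(
    list(samples = as.character(samples), snps = snps, geno = geno),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(gm)
  gm
}

#' Validate a genotype_matrix
#'
#' Checks the class invariants: matrix dimensions agree with sample and SNP
#' metadata, genotype values lie in `{0, 1, 2, NA}`, and positions are
#' strictly increasing within each chromosome.
#'
#' @param gm a `genotype_matrix`.
#' @return `gm`, invisibly; errors describe the first violation found.
#' @export
validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  needed <- c("chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(gm$snps)))
    stop("snps must have columns: ", paste(needed, collapse = ", "))
  if (nrow(gm$geno) != length(gm$samples))
    stop("genotype row count (", nrow(gm$geno), ") != sample count (",
         length(gm$samples), ")")
  if (ncol(gm$geno) != nrow(gm$snps))
    stop("genotype column count (", ncol(gm$geno), ") != SNP count (",
         nrow(gm$snps), ")")
  vals <- gm$geno[!is.na(gm$geno)]
  if (length(vals) && (any(vals < 0L) || any(vals > 2L)))
    stop("genotype values must be 0, 1, 2 or NA")
  if (nrow(gm$snps) > 1) {
    for (ch in unique(gm$snps$chrom)) {
      p <- gm$snps$pos[gm$snps$chrom == ch]
      bad <- which(diff(p) <= 0)
      if (length(bad))
        stop("positions not strictly increasing on ", ch,
             ": record at pos ", p[bad[1] + 1], " follows pos ", p[bad[1]])
    }
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$samples), " samples x ",
      nrow(x$snps), " SNPs on ",
      length(unique(x$snps$chrom)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotype fraction: %.4f\n", miss))
  invisible(x)
}

#' Number of SNPs in a genotype_matrix
#' @param gm a `genotype_matrix`.
#' @return integer SNP count.
#' @export
n_snps <- function(gm) nrow(gm$snps)

#' Subset a genotype_matrix by SNP index
#'
#' @param gm a `genotype_matrix`.
#' @param idx integer vector of SNP column indices (kept in the given order;
#'   must preserve the position sort to keep the object valid).
#' @return a `genotype_matrix` with the selected SNPs.
#' @export
subset_snps <- function(gm, idx) {
  genotype_matrix(gm$samples, gm$snps[idx, , drop = FALSE],
                  gm$geno[, idx, drop = FALSE])
}
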