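#' Read genotypes from VCF or TSV
#'
#' Two formats are supported. `"tsv"` is the package's tabular dialect: a
#' tab-separated file with header `chrom pos ref alt <sample1> <sample2> ...`,
#' one row per SNP, genotypes coded as the alternate-allele count 0/1/2 with
#' `NA` for missing. `"vcf"` is VCF v4.x (parsed with `VariantAnnotation`);
#' multi-allelic records are skipped with a warning and `./.` becomes `NA`.
#'
#' @param path input file path.
#' @param format `"tsv"` or `"vcf"`; defaults from the file extension.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  if (missing(format)) {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA)
  needed <- c("chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(tab)[1:4]))
    stop("TSV genotype file must start with columns: ",
         paste(needed, collapse = ", "))
  samples <- names(tab)[-(1:4)]
  geno <- t(as.matrix(tab[, -(1:4), drop = FALSE]))
  if (nrow(tab) == 0) geno <- matrix(integer(0), nrow = length(samples), ncol = 0)
  snps <- data.frame(chrom = as.character(tab$chrom), pos = as.integer(tab$pos),
                     ref = as.character(tab$ref), alt = as.character(tab$alt),
                     stringsAsFactors = FALSE)
  genotype_matrix(samples, snps, geno)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  alt_list <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt_list)
  keep <- which(nalt == 1L)
  if (length(keep) < length(nalt))
    warning(length(nalt) - length(keep),
            " multi-allelic VCF record(s) skipped")
  rr <- SummarizedExperiment::rowRanges(vcf)[keep]
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  conv <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0|0")] <- 0L
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[x %in% c("1/1", "1|1")] <- 2L
    out
  }
  geno <- t(apply(gt, 2, conv))
  if (length(keep) == 0)
    geno <- matrix(integer(0), nrow = ncol(gt), ncol = 0)
  snps <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)[keep]),
    alt = as.character(unlist(alt_list[keep])),
    stringsAsFactors = FALSE
  )
  genotype_matrix(colnames(gt), snps, geno)
}

#' Write genotypes to VCF or TSV
#'
#' Inverse of [read_genotypes()]: the written file reads back to an equal
#' matrix. The VCF output is a minimal GT-only VCF v4.2 with unphased
#' genotypes and `./.` for missing.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("tsv", "vcf")) {
  if (missing(format)) {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  format <- match.arg(format)
  validate_genotype_matrix(gm)
  if (format == "tsv") {
    tab <- cbind(gm$snps,
                 as.data.frame(t(gm$geno), check.names = FALSE) |>
                   stats::setNames(gm$samples))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=admixsel",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
    if (n_snps(gm) > 0) {
      gt_code <- c("0/0", "0/1", "1/1")
      lines <- vapply(seq_len(n_snps(gm)), function(j) {
        g <- gm$geno[, j]
        gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
        paste(c(gm$snps$chrom[j], gm$snps$pos[j], ".", gm$snps$ref[j],
                gm$snps$alt[j], ".", ".", ".", "GT", gt), collapse = "\t")
      }, character(1))
      writeLines(lines, con)
    }
  }
  invisible(path)
}

#' Filter SNPs by genotype call rate
#'
#' Drops SNPs whose fraction of non-missing genotypes falls below `min_rate`
#' (strictly: a SNP is kept when its call rate is `>= min_rate`). SNP order
#' is preserved and the operation is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param min_rate minimum call rate in `[0, 1]`; the genotyping-rate filter
#'   commonly used for array data is 0.95.
#' @return a filtered `genotype_matrix`.
#' @export
filter_by_call_rate <- function(gm, min_rate) {
  stopifnot(min_rate >= 0, min_rate <= 1)
  validate_genotype_matrix(gm)
  if (n_snps(gm) == 0) return(gm)
  rate <- colMeans(!is.na(gm$geno))
  subset_snps(gm, which(rate >= min_rate))
}
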