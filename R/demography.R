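#' Two-source admixture demography configuration
#'
#' Describes the neutral demographic model the generator emulates: two source
#' populations P and A diverge from a common ancestor `t_split` generations
#' ago, and an admixed population forms in a single pulse `g` generations ago
#' drawing each founding haplotype from P with probability `alpha_P`. Defaults
#' are the model used throughout the package: N = 1000 diploids per
#' population, divergence 1667 generations ago, admixture 100 generations ago
#' with a 24.6% P fraction, mutation rate 1.2e-8 and recombination rate
#' 1.3e-8 per bp per generation, and 3000 independent 1 Mb segments sampled
#' as 48 / 46 / 90 chromosomes from P / admixed / A.
#'
#' For f4-ratio validation an optional outgroup population (splitting from the
#' root `t_outgroup` generations ago) can be added; this is test scaffolding,
#' off by default.
#'
#' Segments are genetically independent. For region calling they are laid out
#' on pseudo-chromosomes of `segments_per_chromosome` segments with a
#' `segment_stride` bp spacing chosen so that the inter-segment genetic
#' distance makes recombination effectively free (g * rec * 4 Mb > 5).
#'
#' @param N diploid population size per population.
#' @param t_split generations since the P/A divergence.
#' @param g generations since the admixture pulse (must be < `t_split`).
#' @param alpha_P admixture fraction contributed by source P.
#' @param mu mutation rate per bp per generation.
#' @param rec recombination rate per bp per generation.
#' @param n_segments number of independent segments.
#' @param segment_length segment length in bp.
#' @param sample_chromosomes named vector of sampled chromosome counts for
#'   `P`, `admixed`, `A` (each must be even and at most 2N).
#' @param include_outgroup add an outgroup population at the root.
#' @param t_outgroup generations since the outgroup split (> `t_split`).
#' @param outgroup_chromosomes sampled chromosomes for the outgroup.
#' @param segments_per_chromosome segments per pseudo-chromosome.
#' @param segment_stride bp offset between segment starts on a
#'   pseudo-chromosome.
#' @return an object of class `demography_config`.
#' @export
demography_config <- function(N = 1000, t_split = 1667, g = 100,
                              alpha_P = 0.246, mu = 1.2e-8, rec = 1.3e-8,
                              n_segments = 3000, segment_length = 1e6,
                              sample_chromosomes = c(P = 48, admixed = 46, A = 90),
                              include_outgroup = FALSE, t_outgroup = 6667,
                              outgroup_chromosomes = 120,
                              segments_per_chromosome = 150,
                              segment_stride = 5e6) {
  stopifnot(N >= 1, g >= 1, g < t_split, alpha_P >= 0, alpha_P <= 1,
            mu >= 0, rec >= 0, n_segments >= 1, segment_length >= 1,
            segment_stride >= segment_length)
  sc <- sample_chromosomes
  if (!all(c("P", "admixed", "A") %in% names(sc)))
    stop("sample_chromosomes must name P, admixed and A")
  if (any(sc %% 2 != 0)) stop("sampled chromosome counts must be even (diploids)")
  if (any(sc > 2 * N)) stop("sample size exceeds 2N")
  if (include_outgroup) {
    stopifnot(t_outgroup > t_split, outgroup_chromosomes %% 2 == 0,
              outgroup_chromosomes <= 2 * N)
  }
  structure(list(N = N, t_split = t_split, g = g, alpha_P = alpha_P, mu = mu,
                 rec = rec, n_segments = n_segments,
                 segment_length = segment_length, sample_chromosomes = sc,
                 include_outgroup = include_outgroup, t_outgroup = t_outgroup,
                 outgroup_chromosomes = outgroup_chromosomes,
                 segments_per_chromosome = segments_per_chromosome,
                 segment_stride = segment_stride),
            class = "demography_config")
}

#' Specification of a post-admixture selected locus
#'
#' Marks one segment of a simulated dataset for forward re-simulation with
#' additive selection favouring the P-derived allele at a focal SNP. The
#' focal-allele initial frequency follows the admixture convention
#' `p0 = f_P * alpha_P + f_A * (1 - alpha_P)` with source frequencies taken
#' at the time of admixture.
#'
#' @param segment 1-based index of the target segment.
#' @param position bp position within the segment; the nearest SNP is used.
#' @param s selection coefficient, `0 <= s < 0.5` (genotype fitnesses
#'   1, 1-s, 1-2s for 2, 1, 0 copies of the favoured allele).
#' @return an object of class `selected_locus_spec`.
#' @export
selected_locus_spec <- function(segment, position, s) {
  stopifnot(segment >= 1, position >= 1, s >= 0, s < 0.5)
  structure(list(segment = as.integer(segment), position = position, s = s),
            class = "selected_locus_spec")
}
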