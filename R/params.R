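#' Slippage model parameters
#'
#' Parameters of the per-cycle duplication/slippage process that generates
#' STR stutter. Each amplification cycle duplicates a molecule with
#' probability `e`; the fresh copy acquires a single-unit slip with
#' probability `s`, which removes one repeat unit with probability `q` and
#' adds one otherwise.
#'
#' @param e Per-cycle duplication probability (amplification efficiency),
#'   in (0, 1].
#' @param s Per-duplication slippage probability, in \[0, 1).
#' @param q Probability that a slip removes (rather than adds) one repeat
#'   unit, in \[0, 1\]. Down-slips dominate in PCR, hence the default 0.8.
#'
#' @return A `stutter_params` list with elements `e`, `s`, `q`.
#' @examples
#' stutter_params()
#' @export
stutter_params <- function(e = 0.95, s = 0.003, q = 0.8) {
  stopifnot(is.numeric(e), length(e) == 1, e > 0, e <= 1)
  stopifnot(is.numeric(s), length(s) == 1, s >= 0, s < 1)
  stopifnot(is.numeric(q), length(q) == 1, q >= 0, q <= 1)
  structure(list(e = e, s = s, q = q), class = "stutter_params")
}

#' Genotyping search grid
#'
#' Defines the candidate space searched by [fit_genotype()]: alleles are
#' taken from the observed repeat-count support expanded by `allele_margin`
#' on each side; amplification cycles and shorter-allele weights come from
#' fixed grids. Candidate patterns are scored by Pearson correlation with
#' the observed histogram over the observed support expanded by
#' `window_pad`; the best score must reach `correlation_min` for a call.
#'
#' @param cycles Integer grid of candidate amplification cycles.
#' @param w Grid of candidate shorter-allele weights for two-allele
#'   mixtures, strictly inside (0, 1). One-allele candidates are always
#'   included separately.
#' @param allele_margin Repeat units added on each side of the observed
#'   support when proposing candidate alleles.
#' @param window_pad Repeat units added on each side of the observed
#'   support to form the correlation window.
#' @param correlation_min Minimum best-fit Pearson correlation for a locus
#'   to be called.
#'
#' @return A `fit_grid` list.
#' @examples
#' fit_grid()
#' @export
fit_grid <- function(cycles = seq(0L, 90L, by = 2L),
                     w = seq(0.05, 0.95, by = 0.05),
                     allele_margin = 2L,
                     window_pad = 5L,
                     correlation_min = 0.95) {
  cycles <- sort(unique(as.integer(cycles)))
  stopifnot(length(cycles) >= 1, all(cycles >= 0))
  stopifnot(length(w) >= 1, all(w > 0), all(w < 1))
  stopifnot(allele_margin >= 0, window_pad >= 0)
  stopifnot(correlation_min > 0, correlation_min <= 1)
  structure(list(cycles = cycles, w = as.numeric(sort(unique(w))),
                 allele_margin = as.integer(allele_margin),
                 window_pad = as.integer(window_pad),
                 correlation_min = correlation_min),
            class = "fit_grid")
}

#' Analysis thresholds
#'
#' The fixed constants of the kit-quality analyses: the pooled-coverage and
#' allele-separation clauses of the heterozygous-locus filter, the
#' failed-cell locus count, the virtual sequencing depth used for
#' consistency, the minimum number of qualifying cells for a kit to be
#' scored, the genotyper's correlation bound, and the minimum mapped reads
#' for a locus to count as sampled.
#'
#' @param min_het_depth Pooled read depth a locus must exceed (strictly) to
#'   enter the heterozygous set. Default 30.
#' @param min_allele_sep Minimum separation (repeat units) between the two
#'   population alleles of an admitted heterozygous locus. Default 3.
#' @param failed_cell_loci A cell with strictly fewer sampled loci than
#'   this is flagged failed. Default 500.
#' @param consistency_reads Number of mapped reads drawn (without
#'   replacement) per cell before computing loci-intersection consistency;
#'   cells with fewer mapped reads are excluded. Default 100000.
#' @param min_cells_per_kit Minimum number of retained cells for a kit to
#'   be scored in the consistency analysis. Default 5.
#' @param correlation_min Genotyper correlation bound (mirrors
#'   [fit_grid()]). Default 0.95.
#' @param min_reads_per_locus_sampled Mapped reads needed for a locus to
#'   count as sampled. Default 1.
#' @param subset_cap Maximum number of k-cell subsets enumerated per
#'   consistency point; larger spaces are sampled. Default 10000.
#'
#' @return A `threshold_config` list.
#' @examples
#' threshold_config()
#' @export
threshold_config <- function(min_het_depth = 30L,
                             min_allele_sep = 3L,
                             failed_cell_loci = 500L,
                             consistency_reads = 100000L,
                             min_cells_per_kit = 5L,
                             correlation_min = 0.95,
                             min_reads_per_locus_sampled = 1L,
                             subset_cap = 10000L) {
  vals <- c(min_het_depth, min_allele_sep, failed_cell_loci,
            consistency_reads, min_cells_per_kit, correlation_min,
            min_reads_per_locus_sampled, subset_cap)
  stopifnot(all(vals > 0))
  structure(list(min_het_depth = as.integer(min_het_depth),
                 min_allele_sep = as.integer(min_allele_sep),
                 failed_cell_loci = as.integer(failed_cell_loci),
                 consistency_reads = as.integer(consistency_reads),
                 min_cells_per_kit = as.integer(min_cells_per_kit),
                 correlation_min = correlation_min,
                 min_reads_per_locus_sampled =
                   as.integer(min_reads_per_locus_sampled),
                 subset_cap = as.integer(subset_cap)),
            class = "threshold_config")
}

# Deterministic child seed from a master seed and a stage/index pair, so
# adding cells or kits never reshuffles the randomness of earlier ones.
# Kept below 2^31 - 1.
child_seed <- function(master, stage, index = 0L) {
  stage_off <- sum(utf8ToInt(stage)) * 131L
  as.integer((as.numeric(master) * 48271 + stage_off * 7919 + index * 104729) %%
               2147483647)
}
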