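#' Generate a clonal diploid genotype for a panel
#'
#' Emulates a clonal cell population grown from a single diploid cell:
#' population-wide, every locus carries at most two distinct alleles.
#' Each locus is heterozygous with probability `het_fraction`; for
#' heterozygous loci the allele separation is drawn uniformly from
#' `min_sep..max_sep` repeat units and placed above or below the reference
#' count with equal probability. Per-locus capture efficiencies (the
#' probability that a molecule is picked up by its targeting probe) are
#' drawn from a Beta distribution.
#'
#' @param panel An [str_panel()] tibble.
#' @param het_fraction Probability a locus is heterozygous, in \[0, 1\].
#' @param min_sep,max_sep Allele separation range (repeat units),
#'   `1 <= min_sep <= max_sep`.
#' @param capture_shape Two Beta shape parameters for per-locus capture
#'   efficiency. Default `c(2, 2)` (mean 0.5).
#' @param seed Integer seed; the clone is deterministic given it.
#'
#' @return A `clone_truth` tibble with columns `locus_id`, `a1`, `a2`
#'   (`a1 <= a2`, repeat counts), `het`, `capture`.
#' @examples
#' p <- synthetic_panel(20, seed = 1)
#' generate_clone(p, het_fraction = 0.5, seed = 2)
#' @export
generate_clone <- function(panel, het_fraction = 0.3, min_sep = 1L,
                           max_sep = 8L, capture_shape = c(2, 2), seed = 1L) {
  if (nrow(panel) == 0) abort("empty panel", class = "strwga_input_error")
  stopifnot(het_fraction >= 0, het_fraction <= 1,
            min_sep >= 1, min_sep <= max_sep)
  withr::local_seed(seed)
  n <- nrow(panel)
  het <- runif(n) < het_fraction
  sep_choices <- seq.int(min_sep, max_sep)
  sep <- ifelse(het,
                sep_choices[sample.int(length(sep_choices), n,
                                       replace = TRUE)],
                0L)
  below <- runif(n) < 0.5
  a1 <- ifelse(het & below, pmax(1L, panel$ref_repeats - sep),
               panel$ref_repeats)
  a2 <- ifelse(het, a1 + sep, a1)
  out <- tibble(locus_id = panel$locus_id,
                a1 = as.integer(a1), a2 = as.integer(a2),
                het = a1 != a2,
                capture = rbeta(n, capture_shape[1], capture_shape[2]))
  class(out) <- c("clone_truth", class(tibble()))
  out
}

#' WGA kit simulation profiles
#'
#' `kit_profile()` validates a single profile; `kit_profiles()` loads the
#' bundled presets (or a user YAML file of the same layout) as a tibble
#' with one row per kit.
#'
#' The bundled presets are synthetic: their numeric values are constrained
#' only by the qualitative, ordinal behaviour reported for the eight kits
#' (RepliG-SC highest yield; Ampli1 least length bias and least locus
#' dropout among PCR kits; PCR-class stutter noise 10-20 cycle-equivalents
#' above MDA-class; GenomePlex/TruePrime mostly failing; bulk near-ideal).
#' See the package vignette for the arithmetic behind the choices.
#'
#' @param name Kit name.
#' @param chemistry One of `"MDA"`, `"PCR"`, `"bulk"`.
#' @param cell_failure_prob Probability a cell is globally degraded.
#' @param locus_dropout_prob Per-locus whole-locus dropout probability.
#' @param allele_dropout_prob Per-allele-copy dropout probability.
#' @param noise_cycles_mean,noise_cycles_sd Per-locus amplification noise,
#'   in PCR-cycle equivalents (Normal, truncated at 0, rounded).
#' @param length_bias_beta Per-repeat-unit relative amplification penalty;
#'   allele weights are proportional to `exp(-beta * repeat_count)`, so
#'   positive values under-amplify the longer allele.
#' @param yield_mean Expected mapped reads per (non-degraded) cell.
#' @param yield_dispersion Negative-binomial size of per-locus read depth;
#'   small values give uneven, overdispersed coverage, `Inf` the Poisson
#'   limit.
#'
#' @return `kit_profile()`: a one-row tibble; `kit_profiles()`: a tibble of
#'   profiles.
#' @examples
#' kit_profiles()$name
#' @export
kit_profile <- function(name, chemistry, cell_failure_prob,
                        locus_dropout_prob, allele_dropout_prob,
                        noise_cycles_mean, noise_cycles_sd,
                        length_bias_beta, yield_mean, yield_dispersion) {
  chemistry <- match.arg(chemistry, c("MDA", "PCR", "bulk"))
  probs <- c(cell_failure_prob, locus_dropout_prob, allele_dropout_prob)
  if (any(probs < 0 | probs > 1)) {
    abort(paste0("kit ", name, ": probabilities must lie in [0, 1]"),
          class = "strwga_validation_error")
  }
  if (noise_cycles_mean < 0 || noise_cycles_sd < 0) {
    abort(paste0("kit ", name, ": noise cycles must be non-negative"),
          class = "strwga_validation_error")
  }
  if (chemistry == "bulk" &&
      (locus_dropout_prob > 0 || allele_dropout_prob > 0 ||
       cell_failure_prob > 0)) {
    abort(paste0("kit ", name, ": a bulk profile has zero dropout"),
          class = "strwga_validation_error")
  }
  if (yield_mean <= 0 || yield_dispersion <= 0) {
    abort(paste0("kit ", name, ": yield parameters must be positive"),
          class = "strwga_validation_error")
  }
  tibble(name = name, chemistry = chemistry,
         cell_failure_prob = cell_failure_prob,
         locus_dropout_prob = locus_dropout_prob,
         allele_dropout_prob = allele_dropout_prob,
         noise_cycles_mean = noise_cycles_mean,
         noise_cycles_sd = noise_cycles_sd,
         length_bias_beta = length_bias_beta,
         yield_mean = yield_mean, yield_dispersion = yield_dispersion)
}

#' @rdname kit_profile
#' @param path Optional YAML file of profiles; defaults to the presets
#'   bundled with the package.
#' @export
kit_profiles <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "kit_profiles.yaml", package = "strwga")
  }
  raw <- yaml::read_yaml(path)$kits
  dplyr::bind_rows(lapply(names(raw), function(nm) {
    do.call(kit_profile, c(list(name = nm), raw[[nm]]))
  }))
}

#' The identity (distortion-free) profile
#'
#' A single-cell profile with zero dropout, zero stutter noise and zero
#' length bias, useful as a positive control: the full simulate-map-genotype
#' loop must recover the clone's genotypes exactly under it.
#'
#' @param yield_mean,yield_dispersion Read yield parameters.
#' @return A one-row profile tibble.
#' @export
identity_profile <- function(yield_mean = 2e5, yield_dispersion = Inf) {
  kit_profile("Identity", "PCR", 0, 0, 0, 0, 0, 0,
              yield_mean, yield_dispersion)
}
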