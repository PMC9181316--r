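# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package code.

# Monte-Carlo oracle for the stutter distribution, in lineage form: a
# uniformly random molecule of the final population existed through c
# cycles during each of which it acquired a slip with probability
# e*s/(1+e) (the chance of being a fresh, slipped copy that cycle);
# slips remove one unit with probability q, else add one, clipped at one
# unit. Slippage does not alter a lineage's branching rate, so sampling
# lineages is distributed exactly as the population-wide length mixture
# of the branching process.
mc_stutter_oracle <- function(allele, cycles, params = stutter_params(),
                              n = 1e5) {
  lam <- params$e * params$s / (1 + params$e)
  lens <- rep(as.integer(allele), n)
  for (cc in seq_len(cycles)) {
    slip <- runif(n) < lam
    dirn <- ifelse(runif(n) < params$q, -1L, 1L)
    lens <- ifelse(slip, pmax(1L, lens + dirn), lens)
  }
  tabulate(lens, nbins = allele + cycles + 5L) / n
}

# Plain-R reimplementation of the per-cycle recursion, operating on an
# arbitrary starting length distribution (used for the linearity and
# equivalence checks).
r_propagate <- function(f, cycles, params = stutter_params()) {
  e <- params$e; s <- params$s; q <- params$q
  n <- length(f)
  for (cc in seq_len(cycles)) {
    g <- (1 + e * (1 - s)) * f +
      e * s * q * c(f[-1], 0) +
      e * s * (1 - q) * c(0, f[-n])
    g[1] <- g[1] + e * s * q * f[1]
    g[n] <- g[n] + e * s * (1 - q) * f[n]
    f <- g / (1 + e)
  }
  f
}

# Brute-force STR-aware aligner: scores a read against every record of the
# length-permuted reference end-to-end (prefix Hamming distance) and
# returns the unique best locus/repeat assignment, or NULL when the read
# is unmappable or ambiguous. This is the defining construction that
# assign_reads() reproduces cheaply.
brute_force_assign <- function(read, perm, max_mm = 2L) {
  best <- function(x) {
    cand <- perm[nchar(perm$seq) >= nchar(x), , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    mm <- vapply(substr(cand$seq, 1, nchar(x)),
                 function(s) sum(charToRaw(s) != charToRaw(x)),
                 integer(1), USE.NAMES = FALSE)
    list(mm = min(mm), hits = cand[mm == min(mm), , drop = FALSE])
  }
  fwd <- best(read)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  rev <- best(rc)
  pick <- NULL
  if (!is.null(fwd) && fwd$mm <= max_mm) pick <- fwd
  if (is.null(pick) && !is.null(rev) && rev$mm <= max_mm) pick <- rev
  if (is.null(pick)) return(NULL)
  hits <- unique(pick$hits[, c("locus_id", "repeats")])
  if (nrow(hits) != 1) return(NULL)
  list(locus_id = hits$locus_id[1], repeats = hits$repeats[1])
}

# Small AC-only panel whose amplicons always fit in a 150 bp read.
tiny_panel <- function(n = 20, seed = 101, units = c(AC = 1),
                       ref_repeats = 8:14) {
  synthetic_panel(n, units = units, ref_repeats = ref_repeats, seed = seed)
}

# Histogram tibble sampled from the package's own stutter model for a
# one- or two-allele genotype (used where the spec's examples sample from
# the simulator itself).
sample_genotype_hist <- function(alleles, w, cycles, depth,
                                 params = stutter_params()) {
  max_len <- max(alleles) + 30L
  d <- vapply(alleles, function(a)
    strwga:::cpp_stutter_distribution(as.integer(a), as.integer(cycles),
                                      params$e, params$s, params$q, max_len),
    numeric(max_len))
  mix <- as.numeric(d %*% w)
  cnt <- rmultinom(1, depth, mix)[, 1]
  nz <- which(cnt > 0)
  tibble::tibble(repeat_count = nz, reads = cnt[nz])
}
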