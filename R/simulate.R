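#' Simulate whole-genome amplification of one cell
#'
#' Applies a kit profile's distortions to a clonal genotype: with
#' probability `cell_failure_prob` the cell is globally degraded (a Beta
#' retention multiplier shrinks both the set of surviving loci and their
#' depth, so a degraded cell samples only a few hundred loci); surviving
#' loci are dropped wholesale at `locus_dropout_prob`; each allele copy is
#' dropped independently at `allele_dropout_prob`; retained allele weights
#' are multiplied by `exp(-length_bias_beta * repeat_count)` and
#' renormalized per locus, under-amplifying the longer allele; each locus
#' receives an amplification-noise cycle count drawn from
#' `Normal(noise_cycles_mean, noise_cycles_sd)`, truncated at 0 and
#' rounded.
#'
#' @param clone A [generate_clone()] tibble.
#' @param profile A one-row kit profile ([kit_profile()]).
#' @param seed Integer seed; the cell is deterministic given it.
#' @param cell_id Cell identifier stored on the result.
#' @param failure_retention_shape Beta shape parameters of the global
#'   retention multiplier drawn for degraded cells. Default `c(1, 12)`
#'   (mean ~0.08).
#'
#' @return A `cell_state` tibble with one row per surviving allele:
#'   `locus_id`, `allele`, `weight` (per-locus weights sum to 1), `cycles`,
#'   `capture`; attributes `cell_id`, `kit`, `failed_sim`, `retention`.
#' @examples
#' p <- synthetic_panel(10, seed = 1)
#' cl <- generate_clone(p, seed = 2)
#' simulate_wga_cell(cl, identity_profile(), seed = 3)
#' @export
simulate_wga_cell <- function(clone, profile, seed, cell_id = "cell",
                              failure_retention_shape = c(1, 12)) {
  stopifnot(nrow(profile) == 1)
  withr::local_seed(seed)
  n <- nrow(clone)
  failed <- runif(1) < profile$cell_failure_prob
  retention <- if (failed) {
    rbeta(1, failure_retention_shape[1], failure_retention_shape[2])
  } else 1
  kept <- runif(n) < (1 - profile$locus_dropout_prob) * retention
  c1 <- runif(n) >= profile$allele_dropout_prob
  c2 <- runif(n) >= profile$allele_dropout_prob
  cycles <- as.integer(round(pmax(0, rnorm(n, profile$noise_cycles_mean,
                                           profile$noise_cycles_sd))))
  beta <- profile$length_bias_beta
  raw1 <- exp(-beta * clone$a1)
  raw2 <- exp(-beta * clone$a2)
  both <- clone$het & c1 & c2
  w1 <- ifelse(both, raw1 / (raw1 + raw2), 1)
  w2 <- raw2 / (raw1 + raw2)

  keep1 <- kept & ifelse(clone$het, c1, c1 | c2)
  keep2 <- kept & clone$het & c2
  rows <- dplyr::bind_rows(
    tibble(locus_id = clone$locus_id[keep1], allele = clone$a1[keep1],
           weight = ifelse(both[keep1], w1[keep1], 1),
           cycles = cycles[keep1], capture = clone$capture[keep1]),
    tibble(locus_id = clone$locus_id[keep2], allele = clone$a2[keep2],
           weight = ifelse(both[keep2], w2[keep2], 1),
           cycles = cycles[keep2], capture = clone$capture[keep2])
  ) %>% arrange(.data$locus_id, .data$allele)
  structure(rows, class = c("cell_state", class(tibble())),
            cell_id = cell_id, kit = profile$name,
            failed_sim = failed, retention = retention)
}

# Draw per-locus read counts and repeat-length counts for a simulated cell.
# The per-locus depth is NB(mean_depth * capture * retention, dispersion)
# (Poisson for infinite dispersion); read lengths are multinomial from the
# mixture of the alleles' stutter distributions at the locus's applied
# cycles. Shared by sample_histograms() and emit_reads() so the direct
# histogram path and the FASTQ path agree read-for-read at zero
# sequencing error.
sample_cell_lengths <- function(cell, mean_depth, dispersion,
                                params = stutter_params(), seed = 1L) {
  withr::local_seed(seed)
  if (nrow(cell) == 0) {
    return(tibble(locus_id = character(), repeat_count = integer(),
                  reads = integer()))
  }
  retention <- attr(cell, "retention") %||% 1
  loci <- unique(cell$locus_id)
  first <- match(loci, cell$locus_id)
  mu <- mean_depth * cell$capture[first] * retention
  depth <- if (is.infinite(dispersion)) {
    rpois(length(mu), mu)
  } else {
    rnbinom(length(mu), size = dispersion, mu = mu)
  }
  max_len <- max(cell$allele) + 30L
  dists <- cpp_stutter_batch(cell$allele, cell$cycles,
                             params$e, params$s, params$q, max_len)
  idx <- split(seq_len(nrow(cell)), factor(cell$locus_id, levels = loci))
  out_locus <- vector("list", length(loci))
  for (j in seq_along(loci)) {
    nl <- depth[j]
    if (nl == 0) next
    rows <- idx[[j]]
    mix <- dists[, rows, drop = FALSE] %*% cell$weight[rows]
    cnt <- rmultinom(1, nl, mix)[, 1]
    nz <- which(cnt > 0)
    out_locus[[j]] <- tibble(locus_id = loci[j], repeat_count = nz,
                             reads = cnt[nz])
  }
  out <- dplyr::bind_rows(out_locus)
  if (nrow(out) == 0) {
    out <- tibble(locus_id = character(), repeat_count = integer(),
                  reads = integer())
  }
  out
}

#' Sample per-locus repeat-number histograms for a simulated cell
#'
#' Draws the cell's targeted-sequencing output directly at the histogram
#' level (read counts per locus per repeat length), skipping read-string
#' emission. At zero sequencing error this is read-for-read identical to
#' [emit_reads()] followed by [histograms_from_fastq()] under the same
#' seed.
#'
#' @param cell A [simulate_wga_cell()] result.
#' @param mean_depth Expected mapped reads per locus at capture 1.
#' @param dispersion Negative-binomial size of per-locus depth (`Inf` for
#'   Poisson).
#' @param params [stutter_params()].
#' @param seed Integer seed.
#'
#' @return A tibble `cell_id`, `locus_id`, `repeat_count`, `reads`.
#' @export
sample_histograms <- function(cell, mean_depth, dispersion = Inf,
                              params = stutter_params(), seed = 1L) {
  h <- sample_cell_lengths(cell, mean_depth, dispersion, params, seed)
  dplyr::bind_cols(tibble(cell_id = rep(attr(cell, "cell_id") %||% "cell",
                                        nrow(h))), h)
}

#' Emit targeted amplicon reads for a simulated cell
#'
#' Writes single-end amplicon reads (sense strand) as 4-line FASTQ with
#' constant `I` qualities: each read is
#' `left_flank + unit^r + right_flank` for a repeat length `r` drawn from
#' the locus's simulated length distribution, truncated to `read_len`,
#' with bases substituted uniformly at `seq_error`. A truth sidecar
#' (`cell_id`, `locus_id`, `allele`, `weight`, `applied_cycles`) is
#' written alongside when `sidecar_path` is given.
#'
#' @param cell A [simulate_wga_cell()] result.
#' @param panel The [str_panel()] the clone was generated from.
#' @param fastq_path Output FASTQ path.
#' @param mean_depth,dispersion,params,seed As in [sample_histograms()].
#' @param read_len Read length (bp); amplicons longer than this are
#'   truncated (flagged with a warning since truncated tracts become
#'   unmappable).
#' @param seq_error Per-base substitution probability.
#' @param sidecar_path Optional truth sidecar TSV path.
#'
#' @return Invisibly, a list with `fastq_path`, `n_reads`, `emitted` (the
#'   per-locus length counts actually written) and `sidecar`.
#' @export
emit_reads <- function(cell, panel, fastq_path, mean_depth,
                       dispersion = Inf, read_len = 150L, seq_error = 0,
                       params = stutter_params(), seed = 1L,
                       sidecar_path = NULL) {
  h <- sample_cell_lengths(cell, mean_depth, dispersion, params, seed)
  cid <- attr(cell, "cell_id") %||% "cell"
  pj <- as_tibble(panel)[, c("locus_id", "unit", "left_flank", "right_flank")]
  h2 <- inner_join(h, pj, by = "locus_id")
  amplicon <- paste0(h2$left_flank, stringr::str_dup(h2$unit, h2$repeat_count),
                     h2$right_flank)
  if (any(nchar(amplicon) > read_len)) {
    warn(paste0(sum(nchar(amplicon) > read_len),
                " length classes exceed read_len and are truncated"))
  }
  seqs <- rep(substr(amplicon, 1, read_len), h2$reads)
  withr::local_seed(child_seed(seed, "seqerr"))
  if (seq_error > 0 && length(seqs) > 0) {
    seqs <- add_substitutions(seqs, seq_error)
  }
  if (length(seqs) == 0) {
    warn("cell emitted zero reads; writing empty FASTQ")
    writeLines(character(0), fastq_path)
  } else {
    ids <- sprintf("%s_r%06d %s", cid, seq_len(length(seqs)),
                   rep(paste0(h2$locus_id, "|", h2$repeat_count), h2$reads))
    x <- Biostrings::DNAStringSet(setNames(seqs, ids))
    qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, fastq_path, format = "fastq",
                                qualities = qual)
  }
  sidecar <- tibble(cell_id = cid, locus_id = cell$locus_id,
                    allele = cell$allele, weight = cell$weight,
                    applied_cycles = cell$cycles) %>%
    semi_join(h, by = "locus_id")
  if (!is.null(sidecar_path)) {
    readr::write_tsv(sidecar, sidecar_path, progress = FALSE)
  }
  invisible(list(fastq_path = fastq_path, n_reads = sum(h$reads),
                 emitted = h, sidecar = sidecar))
}

add_substitutions <- function(seqs, seq_error) {
  bases <- c("A", "C", "G", "T")
  nerr <- rbinom(length(seqs), nchar(seqs), seq_error)
  for (i in which(nerr > 0)) {
    pos <- sample.int(nchar(seqs[i]), nerr[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, cur), 1)
    }
  }
  seqs
}

#' Simulate a multi-kit cell population at the histogram level
#'
#' Runs [simulate_wga_cell()] and [sample_histograms()] for
#' `cells_per_kit` cells under each profile, with per-cell child seeds
#' derived from `seed` by a counter scheme (adding kits or cells never
#' reshuffles earlier cells). Per-locus mean depth for each kit is
#' `yield_mean / n_loci`.
#'
#' @param clone A [generate_clone()] tibble.
#' @param profiles A tibble of kit profiles ([kit_profiles()]).
#' @param cells_per_kit Cells simulated per kit.
#' @param params [stutter_params()].
#' @param seed Master integer seed.
#'
#' @return A list: `histograms` (`cell_id`, `kit`, `locus_id`,
#'   `repeat_count`, `reads`), `cells` (`cell_id`, `kit`, `failed_sim`,
#'   `retention`), `truth` (per-cell surviving alleles with weights and
#'   applied cycles).
#' @export
simulate_cells <- function(clone, profiles, cells_per_kit = 20L,
                           params = stutter_params(), seed = 1L) {
  hist_l <- list(); cells_l <- list(); truth_l <- list()
  n_loci <- nrow(clone)
  for (ki in seq_len(nrow(profiles))) {
    profile <- profiles[ki, ]
    for (ci in seq_len(cells_per_kit)) {
      cid <- sprintf("%s_c%02d", profile$name, ci)
      counter <- ki * 1000L + ci
      cell <- simulate_wga_cell(clone, profile,
                                seed = child_seed(seed, "cell", counter),
                                cell_id = cid)
      h <- sample_histograms(cell, mean_depth = profile$yield_mean / n_loci,
                             dispersion = profile$yield_dispersion,
                             params = params,
                             seed = child_seed(seed, "reads", counter))
      hist_l[[counter]] <- dplyr::bind_cols(
        h[, "cell_id"], tibble(kit = rep(profile$name, nrow(h))),
        h[, c("locus_id", "repeat_count", "reads")])
      cells_l[[counter]] <- tibble(cell_id = cid, kit = profile$name,
                                   failed_sim = attr(cell, "failed_sim"),
                                   retention = attr(cell, "retention"))
      truth_l[[counter]] <- tibble(cell_id = cid, kit = profile$name,
                                   locus_id = cell$locus_id,
                                   allele = cell$allele,
                                   weight = cell$weight,
                                   applied_cycles = cell$cycles)
    }
  }
  list(histograms = dplyr::bind_rows(hist_l),
       cells = dplyr::bind_rows(cells_l),
       truth = dplyr::bind_rows(truth_l))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
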