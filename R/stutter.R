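#' Simulated stutter distribution of an allele
#'
#' Expected repeat-length distribution of the amplification product of a
#' single allele after a number of amplification cycles, under the
#' duplication/slippage process of [stutter_params()]. Writing `f_c` for
#' the normalized length distribution after `c` cycles (with `f_0` a point
#' mass at the allele), one cycle maps
#' `f_{c+1}(x) = ((1 + e(1-s)) f_c(x) + e s (q f_c(x+1) + (1-q) f_c(x-1))) / (1 + e)`.
#' Mass slipping below one repeat unit is clipped to one unit, so every
#' distribution sums to 1 exactly.
#'
#' @param allele Allele repeat count (>= 1).
#' @param cycles Number of amplification cycles (integer >= 0).
#' @param params [stutter_params()].
#' @param max_len Support upper bound; defaults to `allele + 30`.
#'
#' @return A tibble `repeat_count`, `probability`, restricted to positive
#'   probabilities.
#' @examples
#' stutter_distribution(30, 0)            # point mass at 30
#' stutter_distribution(20, 30)
#' @export
stutter_distribution <- function(allele, cycles, params = stutter_params(),
                                 max_len = NULL) {
  if (!is.numeric(allele) || length(allele) != 1 || allele < 1) {
    abort("allele must be a single repeat count >= 1",
          class = "strwga_input_error")
  }
  stopifnot(cycles >= 0)
  if (is.null(max_len)) max_len <- as.integer(allele + 30L)
  p <- cpp_stutter_distribution(as.integer(allele), as.integer(cycles),
                                params$e, params$s, params$q,
                                as.integer(max_len))
  nz <- which(p > 0)
  tibble(repeat_count = nz, probability = p[nz])
}

# Core grid fit; rc/reads are the observed histogram as parallel vectors.
fit_core <- function(rc, reads, grid, params) {
  lo <- max(1L, min(rc) - grid$window_pad)
  hi <- max(rc) + grid$window_pad
  obs <- numeric(hi - lo + 1L)
  obs[rc - lo + 1L] <- reads
  alleles <- seq.int(max(1L, min(rc) - grid$allele_margin),
                     max(rc) + grid$allele_margin)
  cpp_fit_genotype(obs, lo, as.integer(alleles), grid$cycles, grid$w,
                   params$e, params$s, params$q)
}

#' Genotype a repeat-number histogram against simulated stutter patterns
#'
#' Searches one- and two-allele candidates over the [fit_grid()]: a
#' candidate pattern is `w * stutter(a1, c) + (1-w) * stutter(a2, c)` (or a
#' single allele's pattern), scored by Pearson correlation with the
#' observed histogram over the observed support padded by
#' `grid$window_pad`. The best-scoring candidate wins, with ties broken
#' toward fewer alleles, then lower cycles, then smaller separation, then
#' lower first allele. If the best score falls below
#' `grid$correlation_min` the locus is a `no_call` but the best candidate
#' is still reported. `w` is always the weight of the shorter allele;
#' homozygous calls report `w = 1` by convention.
#'
#' @param hist Observed histogram: a tibble/data frame with columns
#'   `repeat_count` and `reads`, or a numeric vector of read counts named
#'   by repeat count.
#' @param grid [fit_grid()].
#' @param params [stutter_params()].
#'
#' @return A `stutter_fit` object; see [glance.stutter_fit()] for the
#'   one-row summary and [tidy.stutter_fit()] for the per-allele view.
#' @examples
#' fit <- fit_genotype(c(`30` = 100))
#' glance(fit)
#' @export
fit_genotype <- function(hist, grid = fit_grid(), params = stutter_params()) {
  if (is.numeric(hist) && !is.null(names(hist))) {
    hist <- tibble(repeat_count = as.integer(names(hist)),
                   reads = as.numeric(hist))
  }
  hist <- as_tibble(hist)
  hist <- hist[hist$reads > 0, , drop = FALSE]
  if (nrow(hist) == 0 || sum(hist$reads) < 1) {
    abort("empty histogram", class = "strwga_input_error")
  }
  f <- fit_core(hist$repeat_count, hist$reads, grid, params)
  structure(list(a1 = f$a1, a2 = f$a2, w = f$w, cycles = f$cycles,
                 correlation = f$correlation, n_alleles = f$n_alleles,
                 status = if (f$correlation >= grid$correlation_min)
                   "called" else "no_call",
                 best_single = f$best_single, best_pair = f$best_pair,
                 total_reads = sum(hist$reads)),
            class = "stutter_fit")
}

#' @export
print.stutter_fit <- function(x, ...) {
  al <- if (x$n_alleles == 2) paste0("(", x$a1, ", ", x$a2, ")") else
    paste0("(", x$a1, ")")
  cat("<stutter_fit> alleles ", al, ", w = ", format(x$w),
      ", cycles = ", x$cycles,
      ", correlation = ", format(x$correlation, digits = 4),
      " [", x$status, "]\n", sep = "")
  invisible(x)
}

#' Tidy a stutter fit
#'
#' @param x A [fit_genotype()] result.
#' @param ... Unused.
#' @return One row per called allele: `allele`, `weight`.
#' @export
tidy.stutter_fit <- function(x, ...) {
  if (x$n_alleles == 2) {
    tibble(allele = c(x$a1, x$a2), weight = c(x$w, 1 - x$w))
  } else {
    tibble(allele = x$a1, weight = 1)
  }
}

#' Summarise a stutter fit in one row
#'
#' @param x A [fit_genotype()] result.
#' @param ... Unused.
#' @return A one-row tibble: `a1`, `a2`, `w`, `cycles`, `correlation`,
#'   `n_alleles`, `status`, `best_single`, `best_pair`, `total_reads`.
#' @export
glance.stutter_fit <- function(x, ...) {
  tibble(a1 = x$a1, a2 = x$a2, w = x$w, cycles = x$cycles,
         correlation = x$correlation, n_alleles = x$n_alleles,
         status = x$status, best_single = x$best_single,
         best_pair = x$best_pair, total_reads = x$total_reads)
}

#' Genotype a table of repeat-number histograms
#'
#' Runs [fit_genotype()] on every `(cell_id, locus_id)` group of a long
#' histogram table.
#'
#' @param histograms Tibble with columns `cell_id`, `locus_id`,
#'   `repeat_count`, `reads` (a missing `cell_id` column is treated as one
#'   pooled sample).
#' @param grid [fit_grid()].
#' @param params [stutter_params()].
#'
#' @return A calls tibble: `cell_id`, `locus_id`, `a1`, `a2`, `w`,
#'   `cycles`, `correlation`, `status`.
#' @export
genotype_histograms <- function(histograms, grid = fit_grid(),
                                params = stutter_params()) {
  h <- as_tibble(histograms)
  if (!"cell_id" %in% names(h)) h$cell_id <- "pooled"
  h <- h[h$reads > 0, , drop = FALSE]
  o <- order(h$cell_id, h$locus_id, h$repeat_count, method = "radix")
  cell <- h$cell_id[o]; locus <- h$locus_id[o]
  rc <- as.integer(h$repeat_count[o]); reads <- as.numeric(h$reads[o])
  grp <- c(TRUE, cell[-1] != cell[-length(cell)] |
             locus[-1] != locus[-length(locus)])
  starts <- which(grp)
  ends <- c(starts[-1] - 1L, length(cell))
  ng <- length(starts)
  a1 <- integer(ng); a2 <- integer(ng); w <- numeric(ng)
  cyc <- integer(ng); corr <- numeric(ng)
  for (g in seq_len(ng)) {
    i <- starts[g]:ends[g]
    f <- fit_core(rc[i], reads[i], grid, params)
    a1[g] <- f$a1; a2[g] <- if (f$n_alleles == 2) f$a2 else NA_integer_
    w[g] <- f$w; cyc[g] <- f$cycles; corr[g] <- f$correlation
  }
  tibble(cell_id = cell[starts], locus_id = locus[starts],
         a1 = a1, a2 = a2, w = w, cycles = cyc, correlation = corr,
         status = ifelse(corr >= grid$correlation_min, "called", "no_call"))
}

#' Per-cell amplification-noise summary
#'
#' Median fitted amplification cycles per cell over called loci whose
#' repeat unit matches `unit_filter` (AC-type loci by default). Cells with
#' fewer than `min_calls` qualifying calls are flagged `low_support`.
#'
#' @param calls A [genotype_histograms()] calls tibble (a `kit` column, if
#'   present, is carried through).
#' @param panel The [str_panel()] providing per-locus repeat units.
#' @param unit_filter Repeat unit to aggregate over. Default `"AC"`.
#' @param min_calls Support threshold for the `low_support` flag.
#'
#' @return A tibble `cell_id` (, `kit`), `median_cycles`, `n_calls`,
#'   `low_support`. Cells with zero qualifying calls are absent.
#' @export
noise_summary <- function(calls, panel, unit_filter = "AC",
                          min_calls = 20L) {
  units <- as_tibble(panel)[, c("locus_id", "unit")]
  x <- calls %>%
    filter(.data$status == "called") %>%
    inner_join(units, by = "locus_id") %>%
    filter(.data$unit == unit_filter)
  grp_cols <- intersect(c("cell_id", "kit"), names(x))
  x %>%
    group_by(dplyr::across(dplyr::all_of(grp_cols))) %>%
    summarise(median_cycles = median(.data$cycles),
              n_calls = dplyr::n(), .groups = "drop") %>%
    mutate(low_support = .data$n_calls < min_calls)
}
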