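#' Loci sampled per cell
#'
#' Number of panel loci with at least
#' `cfg$min_reads_per_locus_sampled` mapped reads in each cell — the
#' amplicon-coverage metric.
#'
#' @param histograms Long histogram tibble (`cell_id`, optional `kit`,
#'   `locus_id`, `repeat_count`, `reads`).
#' @param cfg [threshold_config()].
#'
#' @return A tibble `cell_id` (, `kit`), `loci_sampled`.
#' @export
loci_sampled <- function(histograms, cfg = threshold_config()) {
  grp <- intersect(c("cell_id", "kit"), names(histograms))
  histograms %>%
    group_by(dplyr::across(dplyr::all_of(c(grp, "locus_id")))) %>%
    summarise(reads = sum(.data$reads), .groups = "drop") %>%
    filter(.data$reads >= cfg$min_reads_per_locus_sampled) %>%
    count(dplyr::across(dplyr::all_of(grp)), name = "loci_sampled")
}

#' Failed-cell rate
#'
#' A cell is flagged failed iff it sampled strictly fewer than
#' `cfg$failed_cell_loci` loci.
#'
#' @param counts A [loci_sampled()] tibble (`cell_id`, optional `kit`,
#'   `loci_sampled`). Cells absent from the histogram table should be
#'   included with `loci_sampled = 0` by the caller.
#' @param cfg [threshold_config()].
#'
#' @return A list: `cells` (per-cell flags), `rate` (overall failed
#'   fraction) and, when a `kit` column is present, `by_kit`.
#' @export
failed_cell_rate <- function(counts, cfg = threshold_config()) {
  if (nrow(counts) == 0) {
    abort("no cells", class = "strwga_input_error")
  }
  cells <- counts %>%
    mutate(failed = .data$loci_sampled < cfg$failed_cell_loci)
  out <- list(cells = cells, rate = mean(cells$failed))
  if ("kit" %in% names(cells)) {
    out$by_kit <- cells %>%
      group_by(.data$kit) %>%
      summarise(n_cells = dplyr::n(), n_failed = sum(.data$failed),
                rate = mean(.data$failed), .groups = "drop")
  }
  out
}

#' Population-level heterozygous locus set
#'
#' Pools histograms across all cells per locus, genotypes each pooled
#' histogram, and admits loci that are (a) called with two alleles at
#' least `cfg$min_allele_sep` repeat units apart and (b) covered by
#' strictly more than `cfg$min_het_depth` pooled reads. In a clonal
#' population at most two alleles segregate, so the pooled fit identifies
#' the heterozygous loci whose alleles are far enough apart for their
#' stutter patterns not to overlap.
#'
#' @param histograms Long histogram tibble over all cells.
#' @param cfg [threshold_config()].
#' @param grid [fit_grid()].
#' @param params [stutter_params()].
#'
#' @return A `het_locus_set` tibble: `locus_id`, `a1`, `a2`, `separation`,
#'   `pooled_total`, `w_pooled`.
#' @export
population_het_loci <- function(histograms, cfg = threshold_config(),
                                grid = fit_grid(),
                                params = stutter_params()) {
  pooled <- histograms %>%
    group_by(.data$locus_id, .data$repeat_count) %>%
    summarise(reads = sum(.data$reads), .groups = "drop")
  if (nrow(pooled) == 0) {
    abort("no cells", class = "strwga_input_error")
  }
  totals <- pooled %>%
    group_by(.data$locus_id) %>%
    summarise(pooled_total = sum(.data$reads), .groups = "drop")
  calls <- genotype_histograms(pooled, grid = grid, params = params)
  calls %>%
    inner_join(totals, by = "locus_id") %>%
    filter(.data$status == "called", !is.na(.data$a2),
           .data$a2 - .data$a1 >= cfg$min_allele_sep,
           .data$pooled_total > cfg$min_het_depth) %>%
    mutate(separation = .data$a2 - .data$a1, w_pooled = .data$w) %>%
    select("locus_id", "a1", "a2", "separation", "pooled_total", "w_pooled")
}

#' Per-cell allelic balance at population-heterozygous loci
#'
#' For every admitted heterozygous locus called in a cell, reports the
#' fitted weight `w` of the shorter allele (0.5 is perfectly balanced).
#' Cell-level homozygous calls at these loci are complete allelic
#' dropout: they contribute `w = 1` when the surviving allele is the
#' population's shorter allele and `w = 0` when it is the longer one
#' (calls equidistant from both population alleles are dropped).
#'
#' @param calls A [genotype_histograms()] calls tibble.
#' @param het_set A [population_het_loci()] tibble.
#'
#' @return A tibble `cell_id` (, `kit`), `locus_id`, `w`.
#' @export
allelic_balance <- function(calls, het_set) {
  if (nrow(het_set) == 0) {
    abort("empty heterozygous locus set", class = "strwga_input_error")
  }
  x <- calls %>%
    filter(.data$status == "called") %>%
    inner_join(het_set %>%
                 rename(pop_a1 = "a1", pop_a2 = "a2") %>%
                 select("locus_id", "pop_a1", "pop_a2"),
               by = "locus_id")
  hom <- is.na(x$a2)
  d1 <- abs(x$a1 - x$pop_a1)
  d2 <- abs(x$a1 - x$pop_a2)
  w <- ifelse(hom, ifelse(d1 < d2, 1, 0), x$w)
  keep <- !hom | d1 != d2
  cols <- intersect(c("cell_id", "kit", "locus_id"), names(x))
  dplyr::bind_cols(x[keep, cols], tibble(w = w[keep]))
}

#' Summarise allelic balance per cell
#'
#' @param balance An [allelic_balance()] tibble.
#' @return A tibble `cell_id` (, `kit`), `median_dev` (median
#'   `|w - 0.5|`), `n_loci`.
#' @export
balance_summary <- function(balance) {
  grp <- intersect(c("cell_id", "kit"), names(balance))
  balance %>%
    group_by(dplyr::across(dplyr::all_of(grp))) %>%
    summarise(median_dev = median(abs(.data$w - 0.5)),
              n_loci = dplyr::n(), .groups = "drop")
}

#' Downsample a cell to a fixed number of mapped reads
#'
#' Draws exactly `cfg$consistency_reads` reads without replacement from
#' the cell's per-locus-per-length read counts (multivariate
#' hypergeometric); cells with fewer mapped reads are excluded (`NULL`).
#'
#' @param cell_hist Histogram tibble of one cell.
#' @param cfg [threshold_config()].
#' @param seed Integer seed.
#'
#' @return The downsampled histogram tibble (reads summing exactly to
#'   `cfg$consistency_reads`), or `NULL` if the cell is excluded.
#' @export
downsample_reads <- function(cell_hist, cfg = threshold_config(),
                             seed = 1L) {
  total <- sum(cell_hist$reads)
  r <- cfg$consistency_reads
  if (total < r) return(NULL)
  if (total == r) return(cell_hist)
  withr::local_seed(seed)
  picked <- sample.int(total, r)
  cum <- cumsum(cell_hist$reads)
  cat_idx <- findInterval(picked, c(0, cum), left.open = TRUE)
  new_reads <- tabulate(cat_idx, nbins = nrow(cell_hist))
  out <- cell_hist
  out$reads <- new_reads
  out[out$reads > 0, , drop = FALSE]
}

#' Loci-intersection consistency curve for one kit
#'
#' Mean number of loci jointly sampled by k-cell groups, for each k. All
#' `choose(n, k)` groups are enumerated when there are at most
#' `cfg$subset_cap` of them; otherwise `cfg$subset_cap` seeded random
#' groups are drawn. Input cells must already be downsampled to the
#' common read depth ([downsample_reads()]); a kit with fewer than
#' `cfg$min_cells_per_kit` retained cells is excluded (all-`NA` curve
#' with an `excluded_reason` attribute).
#'
#' @param histograms Downsampled histogram tibble of one kit's retained
#'   cells.
#' @param cfg [threshold_config()].
#' @param ks Group sizes. Default `2:5` (pairs through quintets).
#' @param seed Integer seed for subset sampling.
#'
#' @return A tibble `k`, `mean_intersection`, `n_groups`.
#' @export
consistency_curve <- function(histograms, cfg = threshold_config(),
                              ks = 2:5, seed = 1L) {
  sets <- histograms %>%
    group_by(.data$cell_id, .data$locus_id) %>%
    summarise(reads = sum(.data$reads), .groups = "drop") %>%
    filter(.data$reads >= cfg$min_reads_per_locus_sampled)
  cells <- unique(sets$cell_id)
  n <- length(cells)
  if (n < cfg$min_cells_per_kit) {
    out <- tibble(k = as.integer(ks), mean_intersection = NA_real_,
                  n_groups = 0L)
    attr(out, "excluded_reason") <-
      sprintf("only %d cells retained (< %d)", n, cfg$min_cells_per_kit)
    return(out)
  }
  loci <- unique(sets$locus_id)
  M <- matrix(FALSE, nrow = length(loci), ncol = n,
              dimnames = list(loci, cells))
  M[cbind(match(sets$locus_id, loci), match(sets$cell_id, cells))] <- TRUE
  withr::local_seed(seed)
  res <- lapply(ks, function(k) {
    if (k > n) {
      return(tibble(k = as.integer(k), mean_intersection = NA_real_,
                    n_groups = 0L))
    }
    if (choose(n, k) <= cfg$subset_cap) {
      subsets <- combn(n, k)
    } else {
      subsets <- replicate(cfg$subset_cap, sample.int(n, k))
    }
    sizes <- apply(subsets, 2, function(ss)
      sum(rowSums(M[, ss, drop = FALSE]) == k))
    tibble(k = as.integer(k), mean_intersection = mean(sizes),
           n_groups = ncol(subsets))
  })
  out <- dplyr::bind_rows(res)
  mi <- out$mean_intersection[order(out$k)]
  stopifnot(all(diff(mi[!is.na(mi)]) <= 1e-9))
  out
}

#' Consistency analysis across kits
#'
#' Downsamples every cell to `cfg$consistency_reads` mapped reads
#' (excluding cells below that depth), then computes the
#' [consistency_curve()] per kit; kits with fewer than
#' `cfg$min_cells_per_kit` retained cells are reported as excluded.
#'
#' @param histograms Long histogram tibble with `cell_id` and `kit`.
#' @param cfg [threshold_config()].
#' @param ks Group sizes. Default `2:5`.
#' @param seed Master seed (per-cell and per-kit child seeds are derived
#'   from it).
#'
#' @return A tibble `kit`, `k`, `mean_intersection`, `n_groups`,
#'   `n_cells_retained`, `excluded_reason` (`NA` for scored kits).
#' @export
kit_consistency <- function(histograms, cfg = threshold_config(), ks = 2:5,
                            seed = 1L) {
  kits <- unique(histograms$kit)
  res <- lapply(seq_along(kits), function(ki) {
    h <- histograms %>% filter(.data$kit == kits[ki])
    cells <- unique(h$cell_id)
    ds <- lapply(seq_along(cells), function(ci) {
      downsample_reads(h %>% filter(.data$cell_id == cells[ci]), cfg,
                       seed = child_seed(seed, "downsample",
                                         ki * 1000L + ci))
    })
    ds <- dplyr::bind_rows(ds[!vapply(ds, is.null, logical(1))])
    n_ret <- if (nrow(ds) > 0) dplyr::n_distinct(ds$cell_id) else 0L
    curve <- if (n_ret < cfg$min_cells_per_kit) {
      tibble(k = as.integer(ks), mean_intersection = NA_real_,
             n_groups = 0L)
    } else {
      consistency_curve(ds, cfg, ks,
                        seed = child_seed(seed, "subsets", ki))
    }
    curve %>%
      mutate(kit = kits[ki], n_cells_retained = n_ret,
             excluded_reason = if (n_ret < cfg$min_cells_per_kit) {
               sprintf("only %d cells with >= %d mapped reads", n_ret,
                       cfg$consistency_reads)
             } else NA_character_) %>%
      select("kit", "k", "mean_intersection", "n_groups",
             "n_cells_retained", "excluded_reason")
  })
  dplyr::bind_rows(res)
}
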