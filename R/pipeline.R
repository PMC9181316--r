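#' Pipeline run configuration
#'
#' Bundles everything a reproducible end-to-end run needs. All randomness
#' derives from `seed` through fixed counter-based child seeds, so two
#' runs with the same configuration are identical and adding kits or
#' cells never reshuffles earlier cells.
#'
#' @param n_loci Panel size used when `panel` is `NULL`.
#' @param panel Optional pre-built [str_panel()]; defaults to a
#'   [synthetic_panel()] of `n_loci` loci.
#' @param profiles Kit profiles tibble. Default [kit_profiles()].
#' @param cells_per_kit Cells simulated per kit.
#' @param het_fraction,min_sep,max_sep Clone genotype parameters
#'   ([generate_clone()]).
#' @param thresholds [threshold_config()].
#' @param params [stutter_params()].
#' @param grid [fit_grid()].
#' @param genotype_loci_cap Number of non-heterozygous-set loci genotyped
#'   per cell for the noise analysis (the heterozygous set is always
#'   genotyped). Medians over a few hundred loci per cell are stable;
#'   capping keeps the grid search proportionate.
#' @param unit_filter Repeat unit aggregated in the noise summary.
#' @param seed Master integer seed.
#'
#' @return A `run_config` list.
#' @export
run_config <- function(n_loci = 2000L, panel = NULL,
                       profiles = kit_profiles(), cells_per_kit = 20L,
                       het_fraction = 0.3, min_sep = 1L, max_sep = 8L,
                       thresholds = threshold_config(),
                       params = stutter_params(), grid = fit_grid(),
                       genotype_loci_cap = 300L, unit_filter = "AC",
                       seed = 1L) {
  if (cells_per_kit < 1 || nrow(profiles) < 1) {
    abort("at least one kit and one cell per kit are required",
          class = "strwga_input_error")
  }
  structure(list(n_loci = as.integer(n_loci), panel = panel,
                 profiles = profiles,
                 cells_per_kit = as.integer(cells_per_kit),
                 het_fraction = het_fraction, min_sep = as.integer(min_sep),
                 max_sep = as.integer(max_sep), thresholds = thresholds,
                 params = params, grid = grid,
                 genotype_loci_cap = as.integer(genotype_loci_cap),
                 unit_filter = unit_filter, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full simulate-genotype-metrics pipeline
#'
#' Simulates the configured cell population at the histogram level
#' ([simulate_cells()]), then computes all four kit-quality analyses
#' ([pipeline_metrics()]). When `out_dir` is given, writes the stage
#' outputs (`histograms.tsv`, `calls.tsv`), the four metric tables
#' (`fig2_coverage.tsv`, `fig3_balance.tsv`, `fig4_consistency.tsv`,
#' `fig5_noise.tsv`) and a machine-readable `manifest.json` recording the
#' configuration hash, seed, and counts at every stage.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#'
#' @return A `strwga_run` list: `panel`, `clone`, `cells`, `histograms`,
#'   `truth`, the metric tables (`coverage`, `balance`, `balance_cells`,
#'   `consistency`, `noise`), `het_set`, `calls`, `manifest`, `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  say("stage panel")
  panel <- config$panel %||%
    synthetic_panel(config$n_loci, seed = child_seed(seed, "panel"))
  say("stage clone")
  clone <- generate_clone(panel, het_fraction = config$het_fraction,
                          min_sep = config$min_sep, max_sep = config$max_sep,
                          seed = child_seed(seed, "clone"))
  say("stage simulate")
  sim <- simulate_cells(clone, config$profiles, config$cells_per_kit,
                        params = config$params, seed = seed)
  m <- pipeline_metrics(sim$histograms, sim$cells, panel, config,
                        quiet = quiet)
  run <- c(list(panel = panel, clone = clone, cells = sim$cells,
                histograms = sim$histograms, truth = sim$truth),
           m, list(config = config))
  run$manifest$config_hash <- rlang::hash(config)
  run$manifest$seed <- seed
  class(run) <- "strwga_run"
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Compute the four kit-quality analyses from a histogram table
#'
#' The downstream half of [run_pipeline()]: coverage and failed cells,
#' the population heterozygous set and per-cell allelic balance, the
#' downsampled consistency curves, and the per-cell noise summary. It
#' consumes only the histogram table (plus the cell roster and panel), so
#' a run can be reproduced from a written `histograms.tsv`.
#'
#' @param histograms Long histogram tibble (`cell_id`, `kit`, `locus_id`,
#'   `repeat_count`, `reads`).
#' @param cells Cell roster tibble (`cell_id`, `kit`); cells without any
#'   mapped reads still count (with zero loci).
#' @param panel The [str_panel()].
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#'
#' @return A list: `coverage`, `het_set`, `calls`, `balance`,
#'   `balance_cells`, `consistency`, `noise`, `manifest`.
#' @export
pipeline_metrics <- function(histograms, cells, panel,
                             config = run_config(), quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  cfg <- config$thresholds
  if (nrow(cells) == 0) abort("no cells", class = "strwga_input_error")
  warnings <- character()

  say("stage coverage")
  counts <- loci_sampled(histograms, cfg)
  counts <- cells %>%
    left_join(counts, by = c("cell_id", "kit")) %>%
    mutate(loci_sampled = dplyr::coalesce(.data$loci_sampled, 0L)) %>%
    select("cell_id", "kit", "loci_sampled")
  fcr <- failed_cell_rate(counts, cfg)
  coverage <- fcr$cells

  say("stage population het set")
  het_set <- population_het_loci(histograms, cfg, config$grid,
                                 config$params)
  if (nrow(het_set) == 0) {
    warnings <- c(warnings, "heterozygous locus set is empty")
  }

  say("stage genotyping")
  ac_loci <- panel$locus_id[panel$unit == config$unit_filter]
  extra <- setdiff(ac_loci, het_set$locus_id)
  if (length(extra) > config$genotype_loci_cap) {
    withr::local_seed(child_seed(config$seed, "gtloci"))
    extra <- sample(extra, config$genotype_loci_cap)
  }
  gt_loci <- union(het_set$locus_id, extra)
  calls <- genotype_histograms(
    histograms %>% filter(.data$locus_id %in% gt_loci),
    grid = config$grid, params = config$params) %>%
    left_join(distinct(cells, .data$cell_id, .data$kit), by = "cell_id") %>%
    select("cell_id", "kit", dplyr::everything())
  if (nrow(calls) == 0) warnings <- c(warnings, "no genotype calls")

  say("stage balance")
  balance <- if (nrow(het_set) > 0) {
    allelic_balance(calls, het_set)
  } else {
    tibble(cell_id = character(), kit = character(),
           locus_id = character(), w = numeric())
  }
  balance_cells <- if (nrow(balance) > 0) balance_summary(balance) else
    tibble(cell_id = character(), kit = character(),
           median_dev = numeric(), n_loci = integer())

  say("stage consistency")
  consistency <- kit_consistency(histograms, cfg,
                                 seed = child_seed(config$seed, "cons"))

  say("stage noise")
  noise <- noise_summary(calls, panel, unit_filter = config$unit_filter)

  excluded <- consistency %>%
    filter(!is.na(.data$excluded_reason)) %>%
    distinct(.data$kit, .data$excluded_reason)
  manifest <- list(
    n_loci = nrow(panel),
    n_cells = nrow(cells),
    reads_emitted = sum(histograms$reads),
    reads_mapped = sum(histograms$reads),
    loci_sampled_total = dplyr::n_distinct(histograms$locus_id),
    loci_genotyped = length(gt_loci),
    loci_called = sum(calls$status == "called"),
    het_set_size = nrow(het_set),
    failed_cells = sum(coverage$failed),
    failed_cell_rate = fcr$rate,
    kits_excluded = as.list(setNames(excluded$excluded_reason,
                                     excluded$kit)),
    warnings = warnings)

  list(coverage = coverage, het_set = het_set, calls = calls,
       balance = balance, balance_cells = balance_cells,
       consistency = consistency, noise = noise, manifest = manifest)
}

#' Write a pipeline run to disk
#'
#' @param run A [run_pipeline()] result.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f),
                                       progress = FALSE)
  w(run$histograms, "histograms.tsv")
  w(run$calls, "calls.tsv")
  w(run$coverage, "fig2_coverage.tsv")
  w(run$balance, "fig3_balance.tsv")
  w(run$consistency %>%
      select("kit", "k", "mean_intersection", "n_groups"),
    "fig4_consistency.tsv")
  w(run$noise %>% select("cell_id", "kit", "median_cycles"),
    "fig5_noise.tsv")
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.strwga_run <- function(x, ...) {
  m <- x$manifest
  cat("<strwga_run> ", m$n_cells, " cells, ", m$n_loci, " loci, ",
      format(m$reads_mapped, big.mark = ","), " mapped reads\n",
      "  het set: ", m$het_set_size, " loci; called: ", m$loci_called,
      "; failed cells: ", m$failed_cells,
      " (rate ", format(m$failed_cell_rate, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return A one-row tibble of manifest counts.
#' @export
glance.strwga_run <- function(x, ...) {
  m <- x$manifest
  tibble(n_loci = m$n_loci, n_cells = m$n_cells,
         reads_mapped = m$reads_mapped,
         loci_called = m$loci_called, het_set_size = m$het_set_size,
         failed_cells = m$failed_cells,
         failed_cell_rate = m$failed_cell_rate,
         kits_excluded = length(m$kits_excluded))
}
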