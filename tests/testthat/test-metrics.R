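hist_row <- function(cell, locus, rc, reads, kit = NULL) {
  x <- tibble::tibble(cell_id = cell, locus_id = locus, repeat_count = rc,
                      reads = reads)
  if (!is.null(kit)) x <- dplyr::mutate(x, kit = kit, .after = 1)
  x
}

test_that("loci_sampled counts loci at the configured read threshold", {
  cfg <- threshold_config()
  expect_equal(nrow(loci_sampled(hist_row("c", character(), integer(),
                                          integer()), cfg)), 0L)
  h <- hist_row("c", sprintf("L%03d", 1:700), 12L, 1L)
  expect_equal(loci_sampled(h, cfg)$loci_sampled, 700L)
  # a two-read threshold drops single-read loci
  cfg2 <- threshold_config(min_reads_per_locus_sampled = 2)
  expect_equal(nrow(loci_sampled(h, cfg2)), 0L)
})

test_that("sampled-locus counts match the depth-distribution oracle", {
  p <- synthetic_panel(2000, seed = 401)
  cl <- generate_clone(p, het_fraction = 0, seed = 402)
  cell <- simulate_wga_cell(cl, identity_profile(), seed = 403)
  h <- sample_histograms(cell, mean_depth = 50, dispersion = Inf, seed = 404)
  n <- loci_sampled(h)$loci_sampled
  pr <- 1 - exp(-50 * cl$capture)       # P(Poisson depth >= 1)
  expect_lt(abs(n - sum(pr)), 3 * sqrt(sum(pr * (1 - pr))))
})

test_that("failed-cell flagging is strict at the locus threshold", {
  cfg <- threshold_config()
  one <- function(n) tibble::tibble(cell_id = "c", loci_sampled = n)
  expect_true(failed_cell_rate(one(499L), cfg)$cells$failed)
  expect_equal(failed_cell_rate(one(499L), cfg)$rate, 1)
  expect_false(failed_cell_rate(one(500L), cfg)$cells$failed)
  expect_equal(failed_cell_rate(one(500L), cfg)$rate, 0)
  four <- tibble::tibble(cell_id = paste0("c", 1:4),
                         loci_sampled = c(100L, 600L, 700L, 200L))
  expect_equal(failed_cell_rate(four, cfg)$rate, 0.5)
  expect_error(failed_cell_rate(four[0, ], cfg),
               class = "strwga_input_error")
})

test_that("the population het filter admits exactly the separated, covered loci", {
  withr::local_seed(411)
  mk <- function(locus, alleles, w, depth, cycles = 20) {
    h <- sample_genotype_hist(alleles, w, cycles, depth)
    dplyr::mutate(h, cell_id = "pool", locus_id = locus, .before = 1)
  }
  h <- dplyr::bind_rows(
    mk("sep3", c(10, 13), c(0.5, 0.5), 500),
    mk("sep1", c(29, 30), c(0.5, 0.5), 500),
    mk("hom", 15, 1, 500),
    mk("lowdepth", c(10, 15), c(0.5, 0.5), 30),
    mk("boundary31", c(10, 15), c(0.5, 0.5), 31))
  het <- population_het_loci(h)
  expect_setequal(het$locus_id, c("sep3", "boundary31"))
  expect_true(all(het$separation >= 3))
  expect_true(all(het$pooled_total > 30))
  expect_equal(het$a1[het$locus_id == "sep3"], 10L)
  expect_equal(het$a2[het$locus_id == "sep3"], 13L)
})

test_that("het recovery is complete on a separated clone with no false admissions", {
  p <- tiny_panel(120, seed = 421)
  cl <- generate_clone(p, het_fraction = 0.5, min_sep = 1, max_sep = 8,
                       seed = 422)
  cl$capture <- 1    # uniform capture: every locus clears the 30x clause
  cells <- lapply(1:5, function(i) {
    cell <- simulate_wga_cell(cl, identity_profile(), seed = 430 + i,
                              cell_id = paste0("c", i))
    sample_histograms(cell, mean_depth = 20, seed = 440 + i)
  })
  het <- population_het_loci(dplyr::bind_rows(cells))
  truth_sep3 <- cl$locus_id[cl$het & cl$a2 - cl$a1 >= 3]
  truth_below <- cl$locus_id[!cl$het | cl$a2 - cl$a1 < 3]
  expect_setequal(het$locus_id, truth_sep3)
  expect_length(intersect(het$locus_id, truth_below), 0)
})

test_that("allelic balance reports fitted w and dropout as 0/1", {
  het <- tibble::tibble(locus_id = c("A", "B"), a1 = c(10L, 20L),
                        a2 = c(14L, 25L), separation = c(4L, 5L),
                        pooled_total = 1000L, w_pooled = 0.5)
  calls <- tibble::tibble(
    cell_id = "c1",
    locus_id = c("A", "B"),
    a1 = c(10L, 25L), a2 = c(14L, NA), w = c(0.5, 1),
    cycles = 10L, correlation = 0.99, status = "called")
  b <- allelic_balance(calls, het)
  expect_equal(b$w[b$locus_id == "A"], 0.5)
  expect_equal(b$w[b$locus_id == "B"], 0)   # longer pop allele survived
  calls2 <- dplyr::mutate(calls, a1 = c(10L, 20L))
  b2 <- allelic_balance(calls2, het)
  expect_equal(b2$w[b2$locus_id == "B"], 1) # shorter pop allele survived
  s <- balance_summary(b)
  expect_equal(s$median_dev, median(c(0, 0.5)))
  expect_error(allelic_balance(calls, het[0, ]),
               class = "strwga_input_error")
})

test_that("balanced and length-biased kits separate in the balance metric", {
  p <- tiny_panel(150, seed = 451)
  cl <- generate_clone(p, het_fraction = 1, min_sep = 3, max_sep = 8,
                       seed = 452)
  cl$capture <- 1
  run_kit <- function(prof, seed0) {
    hh <- lapply(1:4, function(i) {
      cell <- simulate_wga_cell(cl, prof, seed = seed0 + i,
                                cell_id = paste0(prof$name, i))
      sample_histograms(cell, mean_depth = 60, seed = seed0 + 100 + i)
    })
    dplyr::bind_rows(hh)
  }
  h_id <- run_kit(identity_profile(), 460)
  h_bias <- run_kit(kit_profile("biased", "PCR", 0, 0, 0, 0, 0,
                                length_bias_beta = 0.06,
                                yield_mean = 1e5, yield_dispersion = Inf),
                    470)
  het <- population_het_loci(dplyr::bind_rows(h_id, h_bias))
  calls_id <- genotype_histograms(h_id)
  calls_bias <- genotype_histograms(h_bias)
  w_id <- allelic_balance(calls_id, het)
  w_bias <- allelic_balance(calls_bias, het)
  expect_lte(abs(median(w_id$w) - 0.5), 0.03)
  expect_gt(median(w_bias$w), 0.5)
})

test_that("downsampling is exact, strict at the threshold, and hypergeometric", {
  cfg <- threshold_config()
  h99 <- hist_row("c", sprintf("L%04d", 1:999), 10L, c(rep(100L, 999)))
  h99$reads[1] <- 99L                      # total 99,999
  expect_null(downsample_reads(h99, cfg, seed = 1))
  h100 <- hist_row("c", sprintf("L%04d", 1:1000), 10L, rep(100L, 1000))
  expect_identical(downsample_reads(h100, cfg, seed = 1), h100)
  h150 <- hist_row("c", sprintf("L%04d", 1:1000), 10L, rep(150L, 1000))
  ds <- downsample_reads(h150, cfg, seed = 2)
  expect_equal(sum(ds$reads), 100000L)
  # hypergeometric oracle on a small configuration
  cfg_small <- threshold_config(consistency_reads = 1000)
  hs <- hist_row("c", c("A", "B", "C"), 10L, c(4000L, 1000L, 500L))
  dss <- downsample_reads(hs, cfg_small, seed = 3)
  expect_equal(sum(dss$reads), 1000L)
  total <- 5500; k <- 1000
  for (i in 1:3) {
    m <- hs$reads[i]
    expv <- k * m / total
    sdv <- sqrt(k * (m / total) * (1 - m / total) *
                  (total - k) / (total - 1))
    expect_lt(abs(dss$reads[i] - expv), 3 * sdv)
  }
})

test_that("consistency curves behave on shared, disjoint and p-sampled sets", {
  cfg <- threshold_config(min_cells_per_kit = 2,
                          min_reads_per_locus_sampled = 1)
  shared <- dplyr::bind_rows(lapply(paste0("c", 1:5), function(cc)
    hist_row(cc, sprintf("L%04d", 1:1000), 10L, 1L)))
  curve <- consistency_curve(shared, cfg, ks = 2:5, seed = 1)
  expect_equal(curve$mean_intersection, rep(1000, 4))

  disjoint <- dplyr::bind_rows(
    hist_row("c1", sprintf("A%03d", 1:50), 10L, 1L),
    hist_row("c2", sprintf("B%03d", 1:50), 10L, 1L))
  curve2 <- consistency_curve(disjoint, cfg, ks = 2, seed = 1)
  expect_equal(curve2$mean_intersection, 0)

  # independent p-sampling: mean intersection ~ L p^k
  withr::local_seed(2)
  L <- 2000; pr <- 0.8
  cells <- dplyr::bind_rows(lapply(paste0("c", 1:8), function(cc) {
    keep <- runif(L) < pr
    hist_row(cc, sprintf("L%04d", which(keep)), 10L, 1L)
  }))
  curve3 <- consistency_curve(cells, cfg, ks = 2:5, seed = 3)
  for (i in seq_len(nrow(curve3))) {
    expv <- L * pr^curve3$k[i]
    expect_lt(abs(curve3$mean_intersection[i] - expv),
              3 * sqrt(L * pr^curve3$k[i] * (1 - pr^curve3$k[i])))
  }
  expect_true(all(diff(curve3$mean_intersection) <= 0))
})

test_that("kits with too few deep cells are excluded from consistency", {
  cfg <- threshold_config(consistency_reads = 1000, min_cells_per_kit = 5)
  h <- dplyr::bind_rows(lapply(paste0("c", 1:4), function(cc)
    hist_row(cc, sprintf("L%03d", 1:100), 10L, 20L, kit = "K")))
  res <- kit_consistency(h, cfg, ks = 2:3, seed = 1)
  expect_true(all(is.na(res$mean_intersection)))
  expect_true(all(!is.na(res$excluded_reason)))
  expect_equal(unique(res$n_cells_retained), 4L)
})
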