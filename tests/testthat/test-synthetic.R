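test_that("clone genotypes follow the requested heterozygosity and separations", {
  p <- tiny_panel(200, seed = 1)
  hom <- generate_clone(p, het_fraction = 0, seed = 2)
  expect_true(all(!hom$het))
  expect_true(all(hom$a1 == hom$a2))

  het <- generate_clone(p, het_fraction = 1, min_sep = 3, max_sep = 3,
                        seed = 3)
  expect_true(all(het$het))
  expect_true(all(het$a2 - het$a1 == 3))
  expect_true(all(het$a1 >= 1))

  # binomial oracle on the heterozygous count
  p10k <- synthetic_panel(10000, seed = 4)
  cl <- generate_clone(p10k, het_fraction = 0.3, seed = 5)
  expect_lt(abs(sum(cl$het) - 3000), 3 * sqrt(10000 * 0.3 * 0.7))

  # determinism
  expect_identical(generate_clone(p, het_fraction = 0.4, seed = 9),
                   generate_clone(p, het_fraction = 0.4, seed = 9))
})

test_that("the identity kit retains both alleles at exact weight 0.5", {
  p <- tiny_panel(100, seed = 11)
  cl <- generate_clone(p, het_fraction = 1, min_sep = 3, max_sep = 6,
                       seed = 12)
  cell <- simulate_wga_cell(cl, identity_profile(), seed = 13)
  expect_equal(nrow(cell), 200L)  # every locus keeps two alleles
  expect_true(all(cell$weight == 0.5))
  expect_true(all(cell$cycles == 0L))
})

test_that("positive length bias shifts weight to the shorter allele", {
  p <- tiny_panel(100, seed = 21)
  cl <- generate_clone(p, het_fraction = 1, min_sep = 3, max_sep = 3,
                       seed = 22)
  prof <- kit_profile("biased", "PCR", 0, 0, 0, 0, 0,
                      length_bias_beta = 0.05, yield_mean = 1e5,
                      yield_dispersion = Inf)
  cell <- simulate_wga_cell(cl, prof, seed = 23)
  short <- cell %>% dplyr::group_by(locus_id) %>%
    dplyr::slice_min(allele, n = 1) %>% dplyr::ungroup()
  expect_true(all(short$weight > 0.5))
  # exact logistic weight for separation 3
  expect_equal(unique(round(short$weight, 10)),
               round(1 / (1 + exp(-0.05 * 3)), 10))
})

test_that("allele dropout counts match the Bernoulli enumeration", {
  p <- synthetic_panel(10000, seed = 31)
  cl <- generate_clone(p, het_fraction = 1, min_sep = 3, max_sep = 6,
                       seed = 32)
  prof <- kit_profile("ado", "PCR", 0, 0, allele_dropout_prob = 0.2,
                      0, 0, 0, 1e5, Inf)
  cell <- simulate_wga_cell(cl, prof, seed = 33)
  n_alleles <- table(factor(table(cell$locus_id), levels = 1:2))
  # exactly one of the two copies drops: 2 p (1-p) per locus
  expect_lt(abs(n_alleles[["1"]] - 2 * 0.2 * 0.8 * 10000),
            3 * sqrt(10000 * 0.32 * 0.68))
  # both drop: p^2 per locus
  lost <- 10000 - length(unique(cell$locus_id))
  expect_lt(abs(lost - 0.04 * 10000), 3 * sqrt(10000 * 0.04 * 0.96))
})

test_that("degraded cells retain far fewer loci than the failure threshold", {
  p <- synthetic_panel(2000, seed = 41)
  cl <- generate_clone(p, seed = 42)
  prof <- kit_profile("fail", "PCR", cell_failure_prob = 1, 0, 0, 0, 0, 0,
                      2e5, Inf)
  loci <- vapply(1:20, function(i) {
    cell <- simulate_wga_cell(cl, prof, seed = 100 + i)
    length(unique(cell$locus_id))
  }, integer(1))
  expect_lt(mean(loci), 500)
})

test_that("per-locus read totals follow the configured depth distribution", {
  p <- tiny_panel(100, seed = 51)
  cl <- generate_clone(p, het_fraction = 0, seed = 52)
  cell <- simulate_wga_cell(cl, identity_profile(), seed = 53)
  h <- sample_histograms(cell, mean_depth = 50, dispersion = Inf, seed = 54)
  # Poisson oracle: total ~ sum of Poisson(50 * capture_l)
  mu <- 50 * cl$capture
  expect_lt(abs(sum(h$reads) - sum(mu)), 3 * sqrt(sum(mu)))
})

test_that("histogram sampling matches the FASTQ path read-for-read", {
  p <- tiny_panel(30, seed = 61)
  cl <- generate_clone(p, het_fraction = 0.5, seed = 62)
  prof <- kit_profiles()[1, ]
  cell <- simulate_wga_cell(cl, prof, seed = 63, cell_id = "cellA")
  h <- sample_histograms(cell, mean_depth = 40, dispersion = 5, seed = 64)
  fq <- withr::local_tempfile(fileext = ".fastq")
  er <- emit_reads(cell, p, fq, mean_depth = 40, dispersion = 5, seed = 64)
  hf <- histograms_from_fastq(fq, p, cell_id = "cellA")
  key <- c("locus_id", "repeat_count", "reads")
  expect_identical(
    as.data.frame(dplyr::arrange(h[key], locus_id, repeat_count)),
    as.data.frame(dplyr::arrange(hf$histograms[key], locus_id, repeat_count)))
  expect_equal(hf$stats$reads_mapped, er$n_reads)
})

test_that("read emission is byte-identical under a fixed seed", {
  p <- tiny_panel(20, seed = 71)
  cl <- generate_clone(p, seed = 72)
  cell <- simulate_wga_cell(cl, kit_profiles()[2, ], seed = 73)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  emit_reads(cell, p, f1, mean_depth = 10, seq_error = 0.01, seed = 74)
  emit_reads(cell, p, f2, mean_depth = 10, seq_error = 0.01, seed = 74)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("error-free homozygous reads carry exactly the true repeat count", {
  tab <- tibble::tibble(chrom = "chr1", start = 60L, end = 120L,
                        locus_id = "L1", unit = "AC", ref_repeats = 30L,
                        left_flank = strrep("GATTACAT", 5),
                        right_flank = strrep("TGCATGGA", 5))
  p <- str_panel(tab)
  cl <- generate_clone(p, het_fraction = 0, seed = 81)
  cell <- simulate_wga_cell(cl, identity_profile(), seed = 82)
  fq <- withr::local_tempfile(fileext = ".fastq")
  emit_reads(cell, p, fq, mean_depth = 50, read_len = 150, seed = 83)
  reads <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
  expect_true(all(grepl(paste0("^", strrep("GATTACAT", 5), strrep("AC", 30),
                               substr(strrep("TGCATGGA", 5), 1, 150 - 100)),
                        reads)))
})

test_that("kit presets encode the reported qualitative orderings", {
  profs <- kit_profiles()
  expect_setequal(profs$name,
                  c("Ampli1", "MALBAC", "PicoPlex", "GenomePlex",
                    "RepliG-SC", "RepliG-Mini", "TruePrime", "Bulk"))
  sc <- profs[profs$chemistry != "bulk", ]
  expect_equal(sc$name[which.max(sc$yield_mean)], "RepliG-SC")
  expect_equal(sc$name[which.min(sc$length_bias_beta)], "Ampli1")
  pcr <- profs[profs$chemistry == "PCR", ]
  expect_equal(pcr$name[which.min(pcr$locus_dropout_prob)], "Ampli1")
  mda <- profs[profs$chemistry == "MDA", ]
  gap <- mean(pcr$noise_cycles_mean) - mean(mda$noise_cycles_mean)
  expect_gte(gap, 10)
  expect_lte(gap, 20)
  expect_setequal(sc$name[rank(-sc$cell_failure_prob) <= 2],
                  c("GenomePlex", "TruePrime"))
  bulk <- profs[profs$chemistry == "bulk", ]
  expect_true(all(bulk$locus_dropout_prob == 0,
                  bulk$allele_dropout_prob == 0,
                  bulk$cell_failure_prob == 0))
})

test_that("profile validation rejects out-of-range parameters", {
  expect_error(kit_profile("bad", "PCR", 1.2, 0, 0, 0, 0, 0, 1e5, 1),
               class = "strwga_validation_error")
  expect_error(kit_profile("bad", "PCR", 0, 0, 0, -5, 0, 0, 1e5, 1),
               class = "strwga_validation_error")
  expect_error(kit_profile("bad", "bulk", 0, 0.1, 0, 0, 0, 0, 1e5, 1),
               class = "strwga_validation_error")
})
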