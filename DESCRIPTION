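Package: strwga
Title: Benchmarking Single-Cell Whole-Genome Amplification with Targeted STR Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for evaluating single-cell
    whole-genome-amplification (WGA) kits through targeted short-tandem-repeat
    (STR) sequencing. Generates clonal diploid cell populations with known STR
    genotypes, distorts them through parameterized per-kit amplification
    profiles (dropout, length-biased allelic imbalance, slippage stutter),
    emits targeted amplicon reads, counts repeats by flank-anchored STR-aware
    mapping, genotypes repeat-number histograms against a simulated PCR
    slippage model, and computes four kit-quality metrics: loci coverage and
    failed-cell rate, heterozygous allelic balance, k-cell loci-intersection
    consistency, and amplification noise in PCR-cycle equivalents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
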