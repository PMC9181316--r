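# Synthetic WGA kit simulation presets (version 1).
#
# All numeric values are synthetic. They are constrained only by the
# qualitative orderings reported for these kits: RepliG-SC gives the best
# overall read yield; Ampli1 has the least allelic length bias and the
# least locus dropout among the PCR-based kits (hence the best balance and
# cross-cell consistency); PCR-based chemistries carry 10-20 PCR-cycle
# equivalents more stutter noise than the isothermal MDA chemistries;
# GenomePlex and TruePrime mostly fail outright; the bulk control is
# near-ideal. See the package vignette for the feasibility arithmetic.
kits:
  Ampli1:
    chemistry: PCR
    cell_failure_prob: 0.10
    locus_dropout_prob: 0.12
    allele_dropout_prob: 0.03
    noise_cycles_mean: 30
    noise_cycles_sd: 3
    length_bias_beta: 0.006
    yield_mean: 280000
    yield_dispersion: 12
  MALBAC:
    chemistry: PCR
    cell_failure_prob: 0.04
    locus_dropout_prob: 0.18
    allele_dropout_prob: 0.07
    noise_cycles_mean: 33
    noise_cycles_sd: 3
    length_bias_beta: 0.020
    yield_mean: 260000
    yield_dispersion: 6
  PicoPlex:
    chemistry: PCR
    cell_failure_prob: 0.08
    locus_dropout_prob: 0.22
    allele_dropout_prob: 0.09
    noise_cycles_mean: 34
    noise_cycles_sd: 3
    length_bias_beta: 0.025
    yield_mean: 280000
    yield_dispersion: 5
  GenomePlex:
    chemistry: PCR
    cell_failure_prob: 0.60
    locus_dropout_prob: 0.35
    allele_dropout_prob: 0.15
    noise_cycles_mean: 36
    noise_cycles_sd: 4
    length_bias_beta: 0.030
    yield_mean: 80000
    yield_dispersion: 4
  RepliG-SC:
    chemistry: MDA
    cell_failure_prob: 0.15
    locus_dropout_prob: 0.02
    allele_dropout_prob: 0.20
    noise_cycles_mean: 18
    noise_cycles_sd: 3
    length_bias_beta: 0.050
    yield_mean: 1100000
    yield_dispersion: 0.5
  RepliG-Mini:
    chemistry: MDA
    cell_failure_prob: 0.05
    locus_dropout_prob: 0.12
    allele_dropout_prob: 0.18
    noise_cycles_mean: 20
    noise_cycles_sd: 3
    length_bias_beta: 0.045
    yield_mean: 350000
    yield_dispersion: 0.7
  TruePrime:
    chemistry: MDA
    cell_failure_prob: 0.70
    locus_dropout_prob: 0.30
    allele_dropout_prob: 0.25
    noise_cycles_mean: 22
    noise_cycles_sd: 3
    length_bias_beta: 0.050
    yield_mean: 60000
    yield_dispersion: 0.6
  Bulk:
    chemistry: bulk
    cell_failure_prob: 0.0
    locus_dropout_prob: 0.0
    allele_dropout_prob: 0.0
    noise_cycles_mean: 8
    noise_cycles_sd: 2
    length_bias_beta: 0.002
    yield_mean: 700000
    yield_dispersion: 25
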