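Package: alleleclim
Title: Drift and Climate Signatures in Worldwide Disease Risk Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether worldwide allele-frequency patterns of
    disease risk SNPs follow the serial-founder (out-of-Africa) drift
    expectation or instead track climate variables. Provides per-population
    allelic statistics (average heterozygosity and average risk-allele
    frequency, raw and baseline-adjusted), great-circle distances with
    migration waypoints, ordinary and weighted regressions on distance and
    climate, frequency-matched SNP resampling null distributions with
    empirical p-values and multiple-testing correction, post-processing of
    per-SNP environmental-association score tables into ranked p-values,
    tail-enrichment permutation tests, gene annotation of SNPs, and a
    serial-founder synthetic data generator so the whole pipeline can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
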