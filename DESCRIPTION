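Package: demuxrescue
Title: Joint Hashing and Genotype-Based Donor Deconvolution for
    Multiplexed Single-Cell Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Joint demultiplexing of pooled single-cell experiments that
    combine cell hashing (HTO) with natural genetic variation.  Matches
    anonymous genetic donor clusters to hashtags by the phi coefficient of
    binarized cell assignments (the "Phi score"), rescues hashing-negative
    droplets using confident genetic singlet calls, reconstructs minimal
    per-donor genotypes from donor-specific overrepresented alleles in
    cellSNP-style allele count matrices, and re-demultiplexes cells against
    the reconstructed genotypes as a sanity check.  Includes a simulator of
    pooled multiplexed experiments (donor genotypes, sparse AD/DP allele
    counts, HTO counts with staining failure, and noisy demultiplexer
    outputs) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
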