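Package: HLApair
Title: HLA Genotyping from Short-Read Alignments by Candidate Selection
    and Pairwise Likelihood Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the most probable pair of HLA alleles per locus at
    four-digit (protein-level) or higher resolution from short-read
    sequencing alignments. Candidate alleles are first selected by
    read counting (quantile pre-selection, optimal-read filtering with
    a 99% SNP-site identity requirement, and leveled protein-group
    ranking with Gaussian z-test p-values), then every pair of
    candidates, including self-pairs, is scored with a total
    log-likelihood combining per-site genotype likelihoods, cross-site
    phase likelihoods, and population allele-frequency priors. Ships a
    synthetic allele-database and paired-end read simulator plus a
    simple placement aligner so the whole pipeline is testable without
    external references.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
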