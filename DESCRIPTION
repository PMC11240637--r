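Package: crhaplo
Title: Forensic Mitochondrial Control-Region Haplotype Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Haplotype collapsing and forensic evaluation of mitochondrial
    control-region (D-loop) sequence databases, as used in wildlife DNA
    forensics. Maps sample sequences onto a reference amplicon, calls
    segregating sites, collapses sequences into named haplotypes, and
    computes per-population diversity statistics: unbiased haplotype
    diversity (Hd), per-site nucleotide diversity (pi), and the random
    match probability (RMP = sum of squared haplotype frequencies) that
    quantifies the evidential weight of an mtDNA match. Pairwise population
    differentiation is measured by Hudson-style Fst from sequence
    differences and Nei Gst (with the Nei-Chesser small-sample correction),
    with permutation significance. Includes a forensic match evaluator
    implementing the two-discrepancy exclusion rule, and a synthetic-data
    generator that reconstructs regional haplotype compositions from
    published summary statistics by exhaustive composition search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
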