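Package: sdAbProfiler
Title: Curation and Region-Level Profiling of Camelid Single-Domain
    Antibody Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Harmonizes heterogeneous single-domain antibody (sdAb/VHH)
    records from tabular or FASTA exports, reconstructs full sequences
    from framework (FR1-FR4) and complementarity-determining region
    (CDR1-CDR3) fragments, delineates FR/CDR boundaries with a
    motif-anchored heuristic or externally supplied numbering, removes
    duplicates and artificially ordered or low-complexity sequences with
    per-rule accounting, and computes per-region, per-species consensus
    conservation, Shannon entropy, amino-acid composition, lysine and
    cysteine distributions, region-length statistics and a
    non-parametric group-comparison battery. A synthetic camelid VHH
    repertoire generator with a known-truth manifest makes every
    pipeline stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
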