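Package: vustruct
Title: Desk-Scale Structural Analysis of Missense Variants of Unknown Significance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable, desk-scale re-implementation of the computational
    core of a variant-to-structure analysis pipeline for missense variants
    of unknown significance (VUS). Maps genomic single-nucleotide variants
    to protein-level consequences against a flat-file transcript catalog,
    reconciles transcript/protein cross-references and halts on
    discrepancies, selects non-redundant and technique-diverse 3D structure
    sets covering each variant, computes spatial-proximity pathogenicity
    scores (PathProx-style) with permutation significance and Ripley-style
    clustering diagnostics, plans HPC-style work with pluggable calculators
    (deterministic stubs stand in for licensed external codes), and renders
    case-wide reports. A fixtures module generates every input format the
    pipeline consumes, deterministically from a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
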