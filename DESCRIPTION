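Package: crisprEdits
Title: Quantification of CRISPR-Cas9 Editing Outcomes from Amplicon Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify non-homologous end joining (NHEJ) editing
    outcomes at a Cas9 cut site from amplicon deep-sequencing reads:
    exact-duplicate read collapsing with a read-frequency filter, primer-based
    target classification, deterministic global (Needleman-Wunsch/Gotoh)
    alignment of each unique sequence to the wildtype amplicon, canonical
    left-normalized variant signatures, NHEJ calling in a window around the
    predicted cut site, per-position match profiles and allele tables.
    Downstream, predicted post-editing translational products (truncation
    point, appended novel residues, epitope retention) and sgRNA guide-site
    selection (NGG PAM scanning, cut-site-to-codon mapping, conserved-site
    pairing between orthologous coding sequences). A seeded amplicon read
    simulator with known editing structure supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
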