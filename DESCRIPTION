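Package: SymDiffDeNovo
Title: De Novo Peptide Sequencing by Symmetric-Difference Spectrum Scoring
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dynamic-programming de novo peptide sequencing over spectrum
    multigraphs, scoring candidate sequences by the symmetric difference
    between their theoretical fragment-mass spectrum and the measured peak
    list (rather than the classical shared peaks count). Provides the best
    and the k best candidate sequences via a matrix graph of dynamic-
    programming states, an offset-aware variant that interprets peaks under
    prefix/suffix ion-type mass offsets (e.g. b/y ions), MGF peak-list
    input/output, a synthetic tandem-MS spectrum simulator with peak
    dropout and noise, and an evaluation harness (rank of the true
    sequence, prefix-mass recall) for comparing scoring models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
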