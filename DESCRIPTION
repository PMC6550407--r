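Package: readthroughr
Title: Statistical Analysis of Stop-Codon Read-Through from Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide whether stop-codon read-through behaves like an
    adaptive, regulated process or like a molecular error under purifying
    selection. Implements read-through rate estimation from ribosome-profiling
    and mRNA-seq abundance (RPKM), detection-bias-free expression binning with
    bootstrap "supergene" rates, stop-codon context (read-through motif)
    composition tests with component shuffling, interspecific conservation
    statistics for post-stop regions (percent identity, codon-position
    contrasts, frame-shifting indels, length differences), hydrophobicity
    comparisons of the extension peptide, and a fully ground-truthed synthetic
    data generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
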