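Package: seqrstools
Title: Simulation and Analysis of SEQRS RNA-Binding Specificity Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing iterative in vitro selection experiments
    (SEQRS: in vitro Selection, high-throughput sEQuencing of RNA, and
    Sequence specificity landscapes) that measure the binding specificity of
    RNA-binding proteins such as the cytoplasmic Poly(A)-binding protein.
    Provides a ground-truth simulator of selection rounds, k-mer counting and
    enrichment landscapes, replicate reproducibility statistics, position
    frequency matrix and sequence-logo construction, class-conditional k-mer
    likelihood classifiers with cross-validated ROC evaluation,
    composition-matched (mono- and dinucleotide-preserving) shuffled
    controls, Mann-Whitney comparisons of motif occupancy, equilibrium
    binding-curve (dissociation constant) and RNA decay (half-life) fitting,
    and two-channel imaging quantification (Manders M1, corrected total cell
    fluorescence, intensity correlation analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
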