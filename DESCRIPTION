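Package: stpsvm
Title: Sequence-Based Detection of Sequential Tri-Disulfide Peptide Toxins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sequential tri-disulfide peptide (STP) toxins -- knottins,
    cyclotides and non-knotted scorpion-toxin-like peptides whose six motif
    cysteines pair C1-C4, C2-C5, C3-C6 -- directly from primary sequence.
    Implements a rule-based cysteine-motif grammar (cysteine loops, minimum-loop
    and positional discard rules, window anchoring), a compact feature calculus
    (normalized proximity lengths, least-loop-length ratio, inter-loop presence,
    residue frequencies) and a radial-kernel support-vector classifier with
    k-fold and repeated random-subsampling evaluation protocols, confusion-matrix
    statistics (including the Matthews correlation coefficient) and ROC/AUC.
    Ships a seeded synthetic-sequence generator for motif-positive and structured
    negative peptides, plus a command-line interface for scanning, feature
    extraction, training, prediction, evaluation and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
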