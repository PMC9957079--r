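Package: haemoQC
Title: Haemolysis Detection for Human Plasma Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality control of human plasma miRNA-seq libraries for red blood
    cell contamination. From a raw miRNA read-count table the package computes
    a per-sample haemolysis metric, the difference in geometric means between a
    signature set of red-blood-cell-associated miRNAs and all remaining
    background miRNAs on TMM-normalised log2 counts-per-million, and labels
    each sample 'Clear' or 'Caution' against a fixed decision threshold.
    Includes sample- and feature-level filtering, a negative-binomial simulator
    of contaminated plasma libraries with ground truth, diagnostic plots, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    edgeR,
    ggplot2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
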