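Package: olfint
Title: Quantitative Analysis of Olfactory Integration Behavior and Calcium Imaging in C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying olfactory integration in Caenorhabditis
    elegans plate chemotaxis assays and stimulus-locked calcium imaging.
    Computes choice indices, incorrect-choice percentages and the
    integration index from plate-count tables; quantifies GCaMP traces
    (baseline-normalised dF/F, windowed ON/OFF responses and
    threshold-crossing OFF latency with neuron-class-specific windows);
    applies a normality-branched statistical comparison procedure
    (t-test/Mann-Whitney, ANOVA-Dunnett/Kruskal-Wallis-Dunn) with star
    annotation; and generates synthetic data with known ground truth via an
    agent-based run-and-tumble plate simulator and a GCaMP-like trace
    synthesizer for validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    multcomp,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
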