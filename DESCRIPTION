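Package: thmix
Title: Tunable Th1-Th2 Differentiation: Network Motif Analysis and
    Synthetic Flow Cytometry
Version: 0.1.0
Authors@R:
    person("thmix", "maintainers", email = "thmix@example.org",
           role = c("aut", "cre"))
Description: Tools for studying CD4+ T-cell differentiation under mixed
    IL-12/IL-4 inputs. Implements the two-transcription-factor
    cross-inhibition/autoactivation network motif (fixed points, stability,
    regime classification, phase diagrams, input-plane co-expression maps,
    trajectory continuity), a two-stage stochastic model in which continuous
    T-bet and GATA3 levels bias independent Bernoulli cytokine-expression
    processes, a calibrated synthetic flow-cytometry data generator over the
    IL-12 x IL-4 input matrix (with isotype and knockout controls), the
    single-cell statistics used to analyse such data (isotype-anchored
    normalization, alpha angles, MFI matrices, rank-1 separability, binned
    bias curves, binary mutual information, BIC modality, quadrant and ratio
    statistics), and a configuration-driven pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
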