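Package: laminarGC
Title: Laminar LFP Spectral Analysis and Conditional Granger Causality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-epoched laminar local field
    potential (LFP) recordings from multi-contact cortical probes:
    spline inverse current-source density (iCSD) and layer-IV alignment,
    multitaper spectral power and coherence with baseline normalization,
    sliding-window time-frequency maps, frequency-resolved conditional
    Granger causality between directed contact pairs with trial-shuffle
    significance thresholds, and attentional modulation statistics
    (modulation indices, dominance-direction matrices, Wilcoxon
    signed-rank tests with false-discovery-rate control, laminar
    compartment pooling). Includes a synthetic laminar-recording
    generator with known ground-truth couplings and condition effects so
    the full pipeline is testable without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
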