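Package: gpephys
Title: Electrophysiology, Morphometry, and Connectivity Analysis of Globus
    Pallidus Neuron Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction and population analysis for ex vivo
    current-clamp recordings of external globus pallidus (GPe) neurons.
    Extracts intrinsic membrane properties (input resistance, rectification,
    capacitance, action-potential waveform metrics, sag, rheobase, f-I
    relations, spontaneous rate) from sweep recordings; decomposes 20 Hz
    IPSP trains with double-exponential subtraction and quantifies
    short-term depression; detects chemical connections and electrical
    coupling in paired recordings and tallies connectivity; computes SWC
    morphometrics including Sholl profiles and branch-order diameters; and
    classifies neuron types with correlation-matrix PCA and Ward
    hierarchical clustering behind a normality-gated group-comparison
    dispatcher. A synthetic-data generator emulating the prototypic and
    arkypallidal populations makes every stage verifiable against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
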