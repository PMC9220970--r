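Package: cassign
Title: Protein Secondary Structure Assignment from C-Alpha Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns three-state protein secondary structure (helix, strand,
    coil) to each residue of a C-alpha-only protein trace. Rotation- and
    translation-invariant geometric features (local chirality-signed
    distances, spatial neighbour counts at several cutoffs, coarse-grained
    hydrogen-bond counts from residue-triangle geometry) are computed over a
    sliding sequence window and classified by a small feed-forward neural
    network trained with stochastic gradient descent. Includes generators for
    labelled synthetic helices, sheets and coils, Q3/confusion-matrix
    evaluation tooling, a portable text model format, and a command-line
    interface covering training, inference, evaluation and synthetic-data
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
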