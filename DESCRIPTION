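Package: gquadfret
Title: Quantification of Protein-Mediated G-Quadruplex Unfolding from smFRET Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying protein-mediated G-quadruplex (GQ)
    unfolding from single-molecule FRET intensity time traces. Implements
    the full analysis chain: background subtraction and single-molecule
    trace filtering, proximity-ratio FRET efficiency computation,
    percent-normalized FRET population histograms, reference-histogram
    subtraction with cumulative-positive-area scoring of unfolded (or
    protein-bound) populations, thresholded population integration,
    Gaussian identification of FRET levels, and weighted Langmuir binding
    isotherm fitting of titration series. A seeded stochastic trace
    generator emulates the underlying spectroscopic state model (Gaussian
    FRET levels, saturation-law state occupancies, photobleaching,
    contaminant molecules) so that every stage of the pipeline can be
    validated by parameter recovery without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
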