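Package: leafflow
Title: Partitioning Leaf Photosynthetic Electron Flow from Combined Gas
    Exchange and Chlorophyll Fluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns raw leaf gas-exchange and pulse-amplitude-modulated
    chlorophyll-fluorescence readings into light-adapted PSII quantum
    efficiency, electron transport rate and the quantum efficiency of CO2
    assimilation; calibrates the linear PSII-CO2 quantum-efficiency
    relation from light-response curves measured under non-photorespiratory
    (2% O2) conditions; and partitions total linear electron flow into
    components attributable to RuBP carboxylation (Jc) and oxygenation
    (Jo), yielding an estimate of photorespiration and the ratios
    Pr/Agross and Jc/Jo. Includes a synthetic-leaf simulator with known
    ground truth for end-to-end verification, instrument-file readers for
    Li-cor-6400-style exports, and study-level trait statistics
    (percent change versus a reference genotype, two-sample t-tests with
    assumption checks, standardized principal component analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
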