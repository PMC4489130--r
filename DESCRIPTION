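Package: divprof
Title: Sequence-Independent Diversity Profiling of Immune Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transforms clonal frequency distributions from high-throughput
    immune repertoire sequencing (AIRR-seq) into Hill-number Diversity and
    Evenness profiles, and couples them to Zipf-Mandelbrot repertoire
    simulation, diversity-profile intersection analysis with sub-repertoire
    delineation, hierarchical clustering with cophenetic validation, and
    feature-selecting sparse linear classification of immunological status
    with nested leave-one-out cross-validation and permutation testing.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
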