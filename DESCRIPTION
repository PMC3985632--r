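Package: chromo3d
Title: Reconstruction of 3D Chromosome Structures from Hi-C Contact Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reconstructs preferred three-dimensional structures of individual
    chromosomes directly from Hi-C chromosomal contact matrices. Raw
    interaction-frequency maps are normalized by an observed/expected marginal
    product, thresholded into contacts and non-contacts, and a parameterized
    tanh-based objective over contact, non-contact and adjacency constraints is
    maximized by steepest gradient ascent with backtracking line search from
    random initializations. Ensembles of optimized models are compared by a
    mirror-aware GDT-HA similarity score, a representative model is selected by
    exact medoid search, models are scored against the constraint set, A/B
    chromatin compartments are detected by principal component analysis of the
    contact map, and a contact-withholding robustness test estimates how well
    unseen contacts are recovered. A synthetic-instance generator provides
    ground-truth structures and Hi-C-like matrices for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
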