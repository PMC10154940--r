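Package: ornametrics
Title: Outline Complexity and Comparative Morphometrics of Sexual Ornaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the shape complexity of closed 2-D trait outlines by
    comparing low- and high-harmonic elliptic Fourier reconstructions (the
    ratio of non-congruent to congruent reconstructed areas), and carries the
    scores through a cross-species comparative analysis of developmental
    costs: trait and body-size morphometrics, per-species sex differences
    with one-sample t-tests and Pearson correlations, and phylogenetic
    generalized least squares regression with Pagel's lambda estimated by
    maximum likelihood. Includes a synthetic-data generator for band-limited
    outlines with controlled harmonic energy, Yule trees, Brownian trait
    evolution, and species-by-sex study panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    mgcv,
    polyclip,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    EBImage,
    jsonlite,
    nlme,
    png,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
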