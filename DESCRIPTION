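Package: clawmorph
Title: Geometric Morphometrics, Lever Mechanics, and Parsimony Analysis of
    Theropod Claws
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis toolkit for the shape, function, and phylogeny of
    dinosaur manual unguals (claws). Implements generalized Procrustes
    analysis with sliding semi-landmarks and tangent-space projection,
    principal component analysis of Procrustes coordinates with thin-plate
    spline deformation grids, a class-3 lever model of claw mechanics
    (mechanical advantage, flexor-tubercle development, hypothesized output
    force), standardized major axis regression and Welch group comparisons,
    and a maximum-parsimony engine for discrete morphological characters
    (Fitch and additive optimization, random-addition Wagner builds with
    NNI/SPR/TBR branch swapping, ensemble consistency and retention indices,
    strict and majority-rule consensus trees). A seeded synthetic-claw
    generator produces landmark, lever, and character-matrix fixtures with
    known ground truth for end-to-end testing.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
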