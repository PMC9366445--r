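Package: morphocontrast
Title: Embedded Group-Contrast Convolutional Networks for Morphological
    Species Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Discriminates morphologically cryptic groups (such as the
    Bemisia tabaci whitefly species complex) from low-resolution grayscale
    specimen photomicrographs.  Implements an embedded group-contrast
    (Siamese) training scheme around a small LeNet-5 style convolutional
    network: all pairwise image contrasts labelled same-group or
    different-group drive a margin-based contrastive loss, yielding a
    low-dimensional feature space in which specimens are identified by
    nearest group centroid.  Includes a seeded synthetic puparium-image
    generator with a controllable between-group effect size, an image
    preparation chain (Von Kries chromatic-adaptation grayscaling,
    percentile exposure normalisation, white-frame cropping, area-average
    step-down to 28x28), confusion-matrix scoring with the multiclass
    Matthews correlation coefficient, sequester-and-retrain jackknife
    validation, permutation MANOVA (Wilks' lambda and Pillai trace), and
    exact t-SNE ordination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
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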