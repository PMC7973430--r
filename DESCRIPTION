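Package: motionsalience
Title: Effectiveness of Movement-Based Animal Signals in Motion Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates movement-based animal displays (lizard-style push-ups,
    head-bobs and tail-flicks) embedded in wind-driven plant-motion noise and
    quantifies their conspicuousness with a motion-channel graph-based visual
    saliency model. Provides a synthetic scene generator with four display and
    four habitat archetypes under a ten-level wind controller, gradient-detector
    motion analysis and signaller masking, Gabor-pyramid/Reichardt-correlation
    saliency maps, receiver-threshold performance vectors, and non-metric
    multidimensional scaling of the resulting factorial design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    utils,
    vegan,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    dplyr,
    ggplot2
Config/testthat/edition: 3
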