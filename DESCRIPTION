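Package: flockBehaviour
Title: Vocalisation-Based Recognition of Flock Behaviour from Field Audio
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies the collective behaviour of vocal bird flocks
    (landing, foraging, flushing) from field audio recordings. Audio is
    segmented into 100 ms sequences and 2048-sample analysis frames, and
    described by Greenwood Function Cepstral Coefficients (GFCC), a
    perceptual cepstral feature whose frequency warping can be tuned to the
    hearing range of the study species (the mel scale is the human special
    case). A branch-and-bound search selects the cepstral coefficients with
    the best class separation under a monotonic between-class-distance
    criterion, and classification uses three pairwise soft-margin RBF
    support vector machines arranged in a one-versus-one directed graph,
    with class-size-scaled misclassification costs and grid-searched
    hyperparameters. Includes day-split and pooled cross-validation
    evaluation protocols, confusion-matrix metrics, and a seeded synthetic
    generator of harmonic flock-call scenes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
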