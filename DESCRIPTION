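Package: igwolf
Title: Improved Grey Wolf Optimization for Feature Selection and Image
    Denoising
Version: 0.1.0
Authors@R:
    person("igwolf", "maintainers", email = "igwolf@example.org",
           role = c("aut", "cre"))
Description: An Improved Grey Wolf Optimizer (IGWO): the canonical grey
    wolf metaheuristic augmented with genetic-algorithm population
    seeding and fitness-sharing niching. Provides a wrapper feature
    selector driven by a cross-validated nearest-neighbour evaluator, a
    PSNR-guided denoising-filter optimizer, watershed-based nodule
    segmentation with boundary tracing, seeded synthetic generators for
    labelled feature tables and CT-like phantom images, and a command
    line interface with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
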