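Package: lightbench
Title: Benchmarking Computational Models of Lightness Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generates the calibrated achromatic displays used in lightness
    research (simultaneous lightness contrast and its variants, White's
    illusion, wedding cake, reversed contrast, dungeon, checkerboard,
    bullseye, and Mondrian patchworks), runs computational models of
    lightness and brightness perception over them (high-pass filtering,
    McCann multiresolution RETINEX, the oriented difference-of-Gaussians
    family ODOG/ODOG-2/LODOG/FLODOG, plus best-effort dynamic-decorrelation
    and intrinsic-image tiers), rescales model output to a common 0-1
    lightness scale, and scores each model's predicted direction of illusion
    against embedded human matching statistics from a large online
    experiment.  Includes a synthetic-observer generator for the matching
    experiment and the paired statistics used to analyse it.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
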