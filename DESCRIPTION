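Package: kneeuq
Title: Cartilage Material Uncertainty in a Hybrid Knee Joint Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Two-stage uncertainty study of knee-joint mechanics under
    variability of the Yeoh hyperelastic constants of articular cartilage.
    A layered sphere-plane elastic-foundation contact solver turns sampled
    material constants into force-indentation curves; the curves drive the
    condylar contact pairs of a planar multibody tibiofemoral model with
    four tension-only nonlinear ligament cables, loaded by stepped external
    moments. Material and ligament parameter spaces are explored with
    deterministic Sobol designs, and the resulting contact forces, angular
    ranges and ligament forces are summarised with coefficient-of-variation
    and relative-range statistics for healthy and osteoarthritic tissue.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
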