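Package: bitemech
Title: Biomechanics of Arthropod Bite Forces Across Mandibular Opening Angles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A first-principles musculoskeletal model of arthropod biting:
    lever mechanics of the mandible joint (apodeme angle, effective levers,
    mechanical advantage, apodeme displacement), pennation and fibre-length
    kinematics for directly and filament-attached muscle fibres, a Gaussian
    muscle force-length relationship, and their composition into a forward
    bite-force model across mandibular opening angles. Includes corrections
    for one-dimensional force-sensor measurements, bounded nonlinear
    least-squares extraction of muscle physiology from bite-force data,
    rigid-body estimation of the mandible rotation axis from multi-pose
    landmarks, a rank-matching algorithm for micro-CT muscle fibre
    morphometry, minimal allometric bite-force models, and synthetic-data
    generators for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
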