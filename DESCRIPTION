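Package: rampetho
Title: Behavioral Quantification of Fishes in Thermal-Ramp (CTmax) Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for video-tracked behavior of fishes subjected to
    acute warming ramps up to loss of equilibrium (LOE). Converts tracker-export
    trajectories (center of mass and snout at 30 Hz) into kinematic series,
    detects and classifies startle-like maneuvers (fast S-bends, single- and
    multi-stage C-bends, withdrawal-like head retractions), profiles turning
    lateralization across the normalized thermal range, extracts opercular
    ventilation metrics (frequency, opening amplitude, opening time and
    velocity) from head-width traces, tallies pectoral fin fanning, splay and
    surfacing bouts, detects Splay-Turn-Glide fixed-action-pattern triplets,
    and quantifies respiratory-locomotor coupling. Includes a synthetic
    experiment generator with exhaustive ground truth so every detector can be
    validated without raw video.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
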