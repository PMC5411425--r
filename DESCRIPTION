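Package: synkey
Title: Hand Grasping Synergies as a Behavioral Biometric
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extraction of spatiotemporal hand synergies from multi-joint
    grasping kinematics by truncated singular value decomposition, and their
    use for identity verification. Provides trial segmentation at a fraction
    of peak angular velocity, fixed-length velocity profiles, ranked synergy
    extraction with variance accounting, template-to-entry matching by
    greedy pairing of shift-aligned summed per-joint correlations, time-bin
    shuffled chance baselines, FAR/FRR curves with equal-error-rate
    estimation, joint-configuration and object-subset sweeps, a planar
    virtual hand for turning movement synergies into admissible end
    postures, a silhouette renderer, and an image-based postural verifier
    built on centroid-normalized radial digit profiles. A seeded synthetic
    population generator emulates multi-subject glove recordings and posture
    photographs so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'kinematics.R'
    'synergy.R'
    'matching.R'
    'evaluation.R'
    'handmodel.R'
    'render.R'
    'imaging.R'
    'synthetic.R'
    'pipeline.R'
    'synkey-package.R'
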