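Package: patchid
Title: Patch-Based Photographic Identification of Individually Patterned Sharks
Version: 0.1.0
Authors@R: person("Maintainer", "patchid", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end photographic identification (photo-ID) toolkit for
    spot-patterned elasmobranchs, built around a four-patch twin-network
    similarity model. Four body regions (head, pectoral/gill area, dorsal
    ahead of the first dorsal fin, dorsal behind it) are extracted from
    rotated-box annotations, scored by per-patch twin similarity networks
    (frozen convolutional backbone, average pooling, small trainable head),
    and fused by a gradient-boosted regression-tree ensemble into a final
    similarity index with a 0.5 same/different decision rule. Includes
    image-based and shark-based (K1 x K2 averaged) evaluation with ROC/AUC,
    a temporal pattern-stability analysis against baseline images, and a
    fully seeded synthetic spot-pattern image generator that emulates adult
    pattern stability and neonate/juvenile ontogenetic pattern drift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    xml2,
    jsonlite,
    digest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
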