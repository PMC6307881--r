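Package: ciliaHTS
Title: Dual-Label Primary Cilium Detection and High-Content Screening Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for high-content ciliogenesis screens.
    Detects primary cilia in multi-channel fluorescence fields by dual
    labeling (acetylated alpha-tubulin axoneme plus pericentrin basal body),
    applies a candidate filter cascade (touching, size, mask-area ratio,
    signal-to-background, local centrosome SD distance), scores per-well
    percent-ciliated values, and computes plate-level screening statistics
    (Z-prime factor, toxicity exclusion, Z-score normalization, hit calling).
    Includes a seeded synthetic field and plate generator with ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    igraph,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
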