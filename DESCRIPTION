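Package: trackforest
Title: Lineage-Tree Cell Tracking from Noisy Instance Segmentations
Version: 0.1.0
Authors@R: person("Track", "Forest", email = "maintainer@trackforest.org", role = c("aut", "cre"))
Description: Tracking-by-detection for 2D timelapse microscopy. Builds cell
    lineage trees from per-frame instance segmentations using a hierarchical
    cache-cascade linker (unique-overlap links, similarity resolution of
    contested links, expanded bounding-box search, rule-based mitosis
    detection, cache matching across short detection gaps), repairs missing
    and false detections (singleton pruning, fragment linking, short-track
    filtering, gap filling), and smooths noisy per-cell class labels along
    each lineage branch. Ships the matching evaluation metrics (IDF1, MOTA,
    division-event F1, per-class F1), readers and writers for label-mask TIFF
    stacks, VIA2 polygon JSON and lineage CSV tables, and a seeded synthetic
    timelapse generator with ground-truth lineages for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
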