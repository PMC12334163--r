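Package: regentrack
Title: Nuclei Tracking, Backtracking and Acquisition Trade-Off Analysis
    for Time-Lapse Recordings of Regenerating Epithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building, manipulating and scoring cell lineage
    forests from 3D+time fluorescence recordings of regenerating
    epithelia. Provides a synthetic recording generator with known
    ground-truth lineages (migration towards a wound, a
    quiescence/burst/decline division schedule, apoptosis, depth
    attenuation, photobleaching with heat-shock recovery, Poisson and
    Gaussian noise over imaging replicates), equal-exposure acquisition
    subsampling, multi-scale blob detection with non-maximum
    suppression, nearest-neighbour lineage linking with flow priors, a
    backtracking tracer with flow interpolation over missing
    detections, acyclic-oriented-graph tracking metrics (DET, TRA,
    precision and recall of detection and linking, proofreading
    effort, depth-stratified scores), and point-cloud registration for
    transferring post-fixation stain labels onto live recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
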