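Package: hsbtw
Title: Balanced Time Warping for Skeleton-Based Rehabilitation Exercise Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative scoring of how closely a patient's recorded
    rehabilitation exercise reproduces an instructor's reference
    performance, from 3D skeletal joint time series. Implements a
    motion-dependent weighted Euclidean pose dissimilarity with attention
    weights derived from the instructor's motion, a shift-window temporal
    alignment solved by dynamic programming with a smoothness and
    no-crossing penalty, decomposition of the aligned distance into
    posture and dynamics components with an anthropometric correction,
    rank-correlation-based balancing of the two components, and a
    leave-two-participants-out cross-validation protocol. A synthetic
    rehabilitation-study generator emulates an instructor plus
    participants performing exercises at graded accuracy levels so the
    whole pipeline is testable without access to recorded patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
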