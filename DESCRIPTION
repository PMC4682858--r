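Package: promtraj
Title: Promoter-Level Expression Trajectory Analysis for Dual-Stimulus Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies CAGE promoter-level expression time courses measured under
    two stimuli into generic and stimulus-specific trajectories using per-promoter
    ANOVA with Benjamini-Hochberg false discovery rate control, detects promoters
    with divergent fold-change dynamics between the stimuli, analyses alternative
    promoter usage and expression coordination among promoters of the same gene,
    performs Fisher's exact test gene-set over-representation with evidence-code
    filtering, and builds correlation-threshold co-expression networks and
    shortest-path protein-protein interaction subnetworks. Includes a synthetic
    time-course generator with planted ground truth so the whole pipeline can be
    exercised and calibrated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
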