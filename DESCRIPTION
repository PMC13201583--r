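Package: ringmetrics
Title: Quantitative Structural Metrics for Hexameric Helicase Rings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative geometric metrics for interpreting atomic models of
    hexameric MCM helicase rings with encircled DNA: dual-distance tight/loose
    classification of the six bipartite ATPase interfaces, the per-subunit
    inter-tier dihedral statistic that bins rings as eclipsed or staggered,
    permuted hexamer-core RMSD comparison across the six cyclic ring settings,
    and Watson-Crick register detection with melted and hairpin-engaged
    nucleotide counting.  Includes a parametric generator of two-tier rings
    and idealized B-DNA duplexes so every metric can be validated against
    programmed ground truth at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
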