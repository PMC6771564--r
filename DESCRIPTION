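Package: trypcycle
Title: Cell-Cycle Timing, Daughter-Cell Asymmetry and Shape Analysis for
    Trypanosome Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the two non-equivalent daughter cells of a
    proliferative Trypanosoma brucei division. Provides the ergodic
    age-distribution machinery of an exponentially growing binary-fission
    population and an estimator converting flagella-connector-remnant marker
    counts into marker persistence times; an agent-based simulator of
    flagellum-label inheritance after RNAi induction, used to compare G1
    durations of new- and old-flagellum daughters; cohort morphometric
    summaries and two-sample tests; a mesh-based anterior-caliber measurement
    replicating sphere-expansion analysis of serial block-face scanning
    electron microscopy cell models; and a synthetic-data generator emulating
    the statistical structure of the underlying microscopy data so the whole
    pipeline is testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
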