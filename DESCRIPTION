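Package: oralproc
Title: Ontogenetic Analysis of Oral Food Processing Efficiency from
    Ethogram-Coded Feeding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying oral food processing efficiency from
    event-level ethogram recordings of primate feeding sequences.
    Computes sequence-level efficiency measures (duration, behavioral
    frequencies, chew number, unique three-behavior patterns), fits
    linear mixed models with crossed random intercepts for food type and
    animal identity, and reports Tukey-adjusted pairwise contrasts
    between age and sex groups.  Includes a simulation framework for
    discontinuous observation (first half, last half, and random
    subsamples of each feeding sequence) with replication-rate scoring
    against the continuous baseline, and a calibrated synthetic-data
    generator for power and type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
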