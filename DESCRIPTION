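Package: cytocore
Title: Virtual-Core Processing of Underway Flow Cytometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing pipeline for continuous underway flow cytometry of
    small phytoplankton. Identifies optimally-positioned particles inside the
    instrument's virtual core with anchored two-piece quantile regressions,
    classifies particles into picophytoplankton populations by sequential
    gating and density-based clustering, converts bead-normalized forward
    scatter to equivalent spherical diameter with a calibrated Mie scattering
    model, derives cellular carbon from a biovolume power law, quantifies
    per-population abundance with flow-rate error propagation, and applies
    instrument and Chauvenet-criterion quality control. Includes a seeded
    cruise simulator that emits ground-truthed event streams, metadata, bead
    tables and matched gating specifications for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    mgcv,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
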