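Package: lipidtraffic
Title: Lipid Traffic Analysis of Multi-Compartment Lipidomics Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Network analysis of lipidomics profiles measured across several
    tissue compartments (e.g. liver, serum, brain, heart, adipose). Lipid
    variables at sum-composition resolution are categorised by where they are
    detected: ubiquitously (A), on an axis between two adjacent compartments
    (B), or in a single compartment only (U). Phenotypes are compared per
    axis with a binary Switch Analysis using Jaccard-Tanimoto coefficients
    and an exact resampling p-value, including detection of variables
    re-routed between axes. A complementary Abundance Analysis quantifies
    per-variable, per-compartment differences via the margin change with
    Student's t-tests against a dependence-corrected threshold and via the
    error-normalised fold change. Includes a seeded synthetic-data generator
    with planted re-routings and abundance effects, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
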