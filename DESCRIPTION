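Package: omegaRT
Title: Chain-Specific Double-Bond Position Annotation of Complex Lipids
    from Retention Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns fatty-acyl omega (n-x) double-bond positions to lipid
    molecular species identified in routine reverse-phase LC-MS/MS runs.
    Builds omega-resolved retention-time databases from stable-isotope-labeling
    experiments with in-silico correction of the deuterium isotope effect on
    retention, aggregates omega-combinations across single-label experiments,
    calibrates databases to new chromatographic conditions via anchor species
    and per-class natural cubic-spline interpolation, and annotates
    identification tables with automated or suggested omega assignments.
    Includes a combinatorial mass-list generator for native and labeled
    species and a synthetic-run simulator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    readxl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
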