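Package: diazocomp
Title: Competitive Controls on Marine Diazotrophs in a Global Box Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced-complexity global box model of the marine nitrogen and
    phosphorus cycles with two phytoplankton functional groups (ordinary
    phytoplankton and nitrogen-fixing diazotrophs), zooplankton and detritus,
    used to contrast two rival explanations for diazotroph persistence:
    selective zooplankton grazing and high-affinity phosphate uptake. Provides
    the CONTR/GRAZ/OLIGO/DECAY experiment configurations, a
    warming-stratification scenario, parameter sensitivity scans with
    tipping-point detection, misfit and bloom diagnostics, and a synthetic
    observation-field generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    ncdf4,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
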