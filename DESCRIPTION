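Package: toothsr
Title: Strontium-90 in Teeth as a Recorder of Environmental Contamination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduction of low-background beta-counting time series to
    decay-corrected strontium-90 activities in tooth ash, with the full
    correction chain (yttrium-90 ingrowth fitting, self-absorption,
    counter efficiency, chemical yield, Poisson detection limits),
    ICP-style determination of stable strontium and calcium by standard
    addition and calibration curve, normalization to activity
    concentration (per g Ca) and specific activity (per g stable Sr), a
    tooth-mineralization chronology model that interprets per-tooth
    activities as a record of a step change in environmental
    strontium-90, tie-corrected nonparametric rank tests, and a
    synthetic herd/laboratory simulator so the whole chain runs
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
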