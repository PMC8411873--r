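Package: fireburden
Title: Health Burden and Exposure Equity of Vegetation-Fire Air Pollution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-simulation analysis pipeline for paired atmospheric-chemistry
    scenarios ("all sources" versus "fires off"): exposure metrics for PM2.5,
    PM10 and ozone (population-weighted means, ADM8h ozone, WHO threshold
    exceedance populations), GEMM and log-linear ozone health-burden
    attribution with the scenario-subtraction method and Monte-Carlo 95%
    uncertainty intervals, station-based model-evaluation statistics (NMBF,
    Pearson r, normalized standard deviation, fire-derived PM isolation), and
    an infant-mortality-rate based exposure-disparity analysis. Includes a
    seeded synthetic-data generator emulating a seasonal fire PM signal over
    a smooth background so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
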