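Package: endoqc
Title: Optical Quality Assurance Bench for Rigid Endoscopes, in Software
Version: 0.1.0
Authors@R: person("endoqc", "maintainers", email = "endoqc@example.org",
    role = c("aut", "cre"))
Description: Re-creates an opto-electronic quality test bench for rigid
    surgical endoscopes as a fully software pipeline: generation of
    black/white line test patterns at seven spatial frequencies plus a
    circular region-of-interest pattern, a parameterised virtual endoscope
    (blur, veiling glare, vignetting, dust, fibre transmission, moisture)
    that renders captures and simulates photocell transmission readings,
    the bench's histogram-quantile contrast statistic and calibrated
    transmission units, a measurement registry with best-of-type baselines,
    database-relative acceptance/rejection decision rules, and longitudinal
    stability, trend and repair-effect reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
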