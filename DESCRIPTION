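Package: earscreen
Title: Exposure-Activity Ratio Screening of Estrogenic Chemical Mixtures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens environmental chemical-monitoring campaigns for estrogenic
    mixture activity using high-throughput in vitro bioactivity data. Aggregates
    per-assay activity concentrations at cutoff (ACC) into a per-chemical potency
    (the 5th percentile, ACC5), converts multi-matrix concentrations (marine
    water, effluent, tissue, fish bile) to exposure-activity ratios (EARs), sums
    them under concentration addition into per-sample mixture scores, derives
    water- and bile-based effect thresholds anchored to 17beta-estradiol
    vitellogenin-induction benchmarks, classifies sites and samples, and
    prioritizes individual chemicals as drivers or contributors of the estrogenic
    response. Includes a synthetic campaign generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
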