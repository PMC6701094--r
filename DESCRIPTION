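Package: windlodge
Title: Quantifying In Situ Stalk Lodging Resistance from Wind Machine Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating stalk lodging resistance of maize cultivars
    tested with a mobile wind machine that steps through increasing wind-speed
    levels. Implements the canopy wind-speed reduction index, the failure wind
    speed as a weighted L1 median of the discrete lodging distribution with
    right-censored survivors, the lodging-resistance function, the cumulative
    lodging index, and between-year reliability via normalized root mean square
    error, together with a seeded stochastic simulator of wind trials
    (stepped wind schedules, distance- and layer-dependent attenuation, and a
    per-plant failure-threshold lodging model) so every statistic can be
    exercised end to end without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
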