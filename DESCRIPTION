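Package: rpdtree
Title: Individual-Based Longevity Analysis with Realized Probability of
    Dying and Regression Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the realized probability of dying (RPD), an
    individual-level relative measure of longevity obtained by comparing
    each subject's survival to the age- and sex-matched expected survival
    from a period life table, together with its logit transform (LRPD).
    Explains LRPD with a binary regression tree grown by recursive
    partitioning with variance-reduction splits, surrogate-based routing
    of missing predictor values, variable importance scaled to 100, and
    10-fold cross-validated average squared error. Includes reading,
    validation and Gompertz generation of period life tables, three-level
    coding (worsened/unchanged/improved) of two-wave predictor changes,
    and a seeded synthetic cohort generator emulating a 35-year mortality
    follow-up of a community cohort aged 60-89 at baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
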