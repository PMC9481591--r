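Package: deplife
Title: Deprivation-Specific Life Tables from Small-Area Mortality Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Constructs sex-, age- and deprivation-specific life tables from
    abridged small-area mortality counts. Provides crude and indirectly
    standardized mortality rates, a Poisson mixed-effects smoothing model with
    restricted cubic splines of age and deprivation-quintile-by-age
    interactions, cross-validated knot selection, delta-method uncertainty for
    predicted rates, complete life-table construction, and population-weighted
    geographic aggregation of life expectancy. Includes a census-tract-like
    synthetic data generator with a known Gompertz-Makeham hazard and
    log-normal area frailty, giving a ground-truth life-expectancy oracle for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    lme4,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
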