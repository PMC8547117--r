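Package: premort
Title: Premature Mortality from Life-Table Age-at-Death Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures premature mortality from period life tables using three
    approaches: classic absolute threshold measures (banded death rates,
    threshold fractions, potential years of life lost), a relative
    three-component mixture of infant, premature and senescent age-at-death
    distributions with skew-normal components, and a Bayesian hierarchical
    mixture in which a group of populations shares one senescent skew-normal
    component while each population keeps its own premature component and
    mixture weight. Includes a reader and writer for Human Mortality Database
    1x1 period life-table files, centered/direct skew-normal parametrization
    utilities, an adaptive Metropolis sampler with split R-hat diagnostics,
    and a synthetic life-table generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
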