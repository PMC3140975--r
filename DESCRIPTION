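Package: dropenc
Title: Statistical Design and Simulation of Single Target Cell Encapsulation in Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the random encapsulation of cells from a heterogeneous
    suspension into nanoliter droplets. Provides the binomial occupancy and
    Poisson cell-count laws and their combination into the single-target-cell
    probability, Stirling-approximation evaluation of binomial probabilities,
    Chebyshev/law-of-large-numbers minimum sample-size determination at a
    stated confidence and tolerance, design equations linking cell loading
    concentration, droplet volume and cell volume, a seeded Monte Carlo
    droplet-array simulator, estimators for the Poisson loading rate with
    confidence intervals, and a parameter-recovery study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
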