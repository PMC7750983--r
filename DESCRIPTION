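Package: icmolar
Title: Intraspecific Tests of the Inhibitory Cascade Model on Molar Size Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing the inhibitory cascade model (ICM) and its
    length-only variant, the molar module component (MMC), on intraspecific
    samples of lower molar rows. Reads replicated crown measurements,
    estimates ANOVA repeatability, derives molar size-ratio phenotypes,
    fits a Bayesian multivariate-Gaussian posterior for the mean and
    covariance of molar sizes via a conjugate Gibbs sampler, and evaluates
    the six ICM predictions for means, variances, and covariances as
    observed/theoretical ratios with 95% highest-posterior-density
    intervals. Includes standing-variation diagnostics (coefficients of
    variation, sign tests, pairwise Mann-Whitney comparisons with
    Bonferroni correction), resampling experiments for minimum sample
    size and for composite molar rows assembled from isolated teeth, and
    a synthetic molar-row generator with known statistical structure for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    coda,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
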