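Package: gmpcomb
Title: Generalized Mean P-Values for Combining Dependent Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combines K p-values with generalized mean p-values (GMPs),
    the family of statistics interpolating the minimum, harmonic mean,
    geometric mean, arithmetic mean and maximum of the constituent
    p-values. Provides significance thresholds derived from generalized
    central limit theorem (GCLT), via quantiles of extremal stable
    distributions, and worst-case thresholds from robust risk analysis
    (RRA), together with the inverse maps between them; closed testing
    procedures for subsets of p-values controlling the strong-sense
    family-wise error rate; a model-averaged Bayes factor interpretation;
    an equicorrelated Wishart-Multivariate-Gamma simulator of dependent
    likelihood ratio tests; and a simulation harness for power and
    false-positive-rate studies against Bonferroni, Sidak, Simes and
    Fisher comparators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
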