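Package: rqrdiag
Title: Randomized Quantile Residual Diagnostics for Zero-Inflated Count
    Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Goodness-of-fit diagnostics for mixed-effects regression
    models of overdispersed, zero-heavy count data such as microbiome
    OTU (operational taxonomic unit) read counts.  Implements randomized
    quantile residuals (Dunn-Smyth residuals) for Poisson, negative
    binomial, zero-inflated and hurdle (zero-modified) mixed models
    fitted by maximum likelihood, Shapiro-Wilk based overall
    goodness-of-fit testing with replicated-residual p-value averaging,
    a count-data simulator with structural zeros, sequencing-depth
    offsets and crossed random effects, and a Monte-Carlo study runner
    that measures type-I error and power of the residual-based tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmmTMB,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
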