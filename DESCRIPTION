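Package: siginfo
Title: Information-Theoretic Analysis of Cytokine Signalling Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies robustness and information transfer in single-cell
    cytokine signalling data. Estimates Mutual Information between STAT3
    expression and STAT3-Y705 phosphorylation by Gaussian kernel density
    estimation and adaptive numerical integration, and Channel Capacity
    between a discrete IL-6 dose ladder and the continuous pSTAT3 response
    by Blahut-Arimoto iteration or a classifier-based estimator. Includes
    the accompanying statistical testing scheme (group standardisation,
    Kolmogorov-Smirnov normality screening, N-way and 1-way ANOVA, unbiased
    Cohen's d with effect-size classification) and a phenomenological
    single-cell simulator of heterogeneous STAT3 expression and dose-
    dependent phosphorylation across genotype presets, so the full analysis
    pipeline can be exercised end-to-end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
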