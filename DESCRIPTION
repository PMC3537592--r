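Package: pgain
Title: The p-Gain Statistic for Metabolite Ratio Association Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hypothesis-free testing of ratios between metabolite
    concentrations in genome-wide and metabolome-wide association studies
    using the p-gain statistic, the ratio of the smaller single-metabolite
    association p-value to the ratio association p-value. Provides the
    closed-form null distribution of the conservative p-gain (the ratio of
    two independent uniform p-values), Bonferroni-corrected critical values
    B/(2*alpha), Gaussian-copula Monte Carlo simulation of the p-gain under
    arbitrary correlation between the metabolites and their ratio, bootstrap
    resampling of the p-gain as a function of sample size, a synthetic
    cohort generator with known ground truth, and delimited-table input and
    output with a command-line interface. All p-values and p-gains are
    carried on the log10 scale so that association signals far beyond
    double-precision range remain finite.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
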