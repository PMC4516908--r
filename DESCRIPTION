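Package: mrsummary
Title: Mendelian Randomization with Summarized Genetic Association Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Causal effect estimation from summarized genetic association
    data in the two-sample Mendelian randomization design. Implements the
    ratio and inverse-variance weighted (IVW) estimators, a likelihood-based
    estimator fitted by profile maximum likelihood or by Markov chain Monte
    Carlo, with extensions for correlated variants (linkage disequilibrium)
    and for overlapping exposure and outcome samples; a likelihood-ratio
    heterogeneity (overidentification) test of the common causal effect;
    instrument-validity screening via covariate association testing, allele
    scores and conservative/liberal instrument sets; and a synthetic-data
    generator for one-sample, subsample and two-sample designs at the
    individual and summary level.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools
Suggests: testthat (>= 3.0.0), optparse, jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
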