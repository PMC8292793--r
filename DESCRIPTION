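Package: srmassess
Title: Norm-Referenced Family Assessment with the Social Relations Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements Social Relations Model (SRM) assessment of a single
    four-person family measured with a round-robin design. The 12 directed
    dyadic scores are decomposed into 21 ANOVA effects (one family effect,
    four actor effects, four partner effects, twelve relationship effects).
    Published population parameters of the latent SRM components estimated by
    confirmatory factor analysis on a normative sample - means, variances,
    generalized and dyadic reciprocities - are transformed by exact linear
    propagation into the sampling distribution of each ANOVA score, so that
    per-effect Z scores and two-sided p-values can be computed without access
    to the normative sample's raw data. Includes a multivariate-normal
    simulator of round-robin families for validating the transformation, file
    readers and writers for dyad tables and norm-parameter files, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
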