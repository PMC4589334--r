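Package: hairpincs
Title: Beta-Hairpin Motif Classification from NMR Chemical Shifts
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Classifies protein sequence fragments as beta-hairpin or
    non-hairpin supersecondary structure from backbone NMR chemical
    shifts.  Fragments are summarised as six-nuclei (C, CA, CB, HN, HA,
    N) averaged chemical-shift vectors and classified with a two-class
    quadratic discriminant built from per-class Gaussian models,
    including an error-allowed-scope correction coefficient.  Also
    provides one-way ANOVA feature screening, P-P normality diagnostics,
    stratified k-fold cross-validation with leave-one-nucleus-out
    ablation and nucleus-importance ranking, pluggable baseline
    classifiers, and a synthetic fragment generator with a Monte Carlo
    Bayes-error oracle so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    e1071,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
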