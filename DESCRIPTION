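Package: hybridcor
Title: Mid-Parent Expression-Trait Correlation Analysis for Factorial Hybrid Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genes whose mid-parent seedling expression correlates
    with hybrid performance and heterosis for grain yield and grain dry matter
    content in factorial crosses between two heterotic groups. Implements a
    spike-in based reliability screen, an empirical-Bayes moderated F-test
    with nested pairwise tests, Pearson correlation of mid-parent expression
    with hybrid traits (t-tests, Benjamini-Hochberg FDR, BCa bootstrap
    confidence intervals, Monte Carlo permutation tests), a two-step gene-set
    selection with iterative co-expression expansion, line-resampling
    cross-validation of ranking stability, hypergeometric category
    enrichment, and a seeded synthetic-data generator that emulates a
    7 x 14 factorial study design end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), limma, boot, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
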