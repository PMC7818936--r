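Package: minicrispr
Title: Minimal CRISPR-Cas9 Library Design and Pooled Screen Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of pooled genome-wide CRISPR-Cas9 loss-of-fitness
    screens and design of minimal (two guides per gene) knockout libraries.
    Implements plasmid-count filtering, reads-per-million normalisation and
    pseudo-count log2 fold-changes; an empirical per-guide efficacy score
    based on the two-sample Kolmogorov-Smirnov statistic against
    non-targeting controls; tiered (green/amber/red) guide selection from a
    multi-library reference with off-target and efficacy filters and
    source-precedence ranking; and a benchmarking suite (essential-gene
    recall curves, standardised partial AROC, fold-change thresholds at a
    target FDR, dependency calls, average precision, guide down-sampling,
    Lorenz/Gini plasmid QC). A negative-binomial screen simulator with full
    ground truth makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
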