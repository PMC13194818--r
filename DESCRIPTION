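Package: ragvar
Title: Retrieval-Augmented Variant Interpretation and Benchmark Evaluation
Version: 0.1.0
Authors@R:
    person("ragvar", "developers", email = "ragvar@example.org", role = c("aut", "cre"))
Description: A retrieval-augmented generation (RAG) pipeline for human genomic
    variant interpretation, together with the benchmark-construction and
    statistical-evaluation machinery needed to compare answer-generation
    systems. The pipeline extracts an rs number or HGVS notation from a
    free-text question, normalizes it to a GRCh38 genomic allele, retrieves
    the integrated variant annotation (allele frequencies, clinical
    significance, pathogenicity predictions) from a variant-database client,
    and assembles a three-section prompt for a pluggable large-language-model
    backend. Shipped fixture backends (a lookup-table recoder, a
    fixture-directory variant service, and a deterministic stub model) make
    the whole pipeline testable offline. The evaluation half implements a
    five-criterion 0-10 rubric with winner tallies, percentile bootstrap
    confidence intervals, the Friedman test with Kendall's W, Holm-adjusted
    paired Wilcoxon signed-rank tests, ICC(2,2), quadratic-weighted Cohen's
    kappa, and a score-table simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
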