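---
title: "Retrieval-augmented variant interpretation and how it is evaluated"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval-augmented variant interpretation and how it is evaluated}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragvar)
```

## The problem

General-purpose large language models answer questions about human genomic
variants fluently but unreliably: they hallucinate allele frequencies, attach
variants to the wrong gene, and invent clinical interpretations. For variant
interpretation — where a wrong gene–variant association can mislead a
clinical assessment — this failure mode is disqualifying. The standard
mitigation is retrieval-augmented generation (RAG): look the variant up in a
curated database, inject the retrieved record into the prompt, and instruct
the model to ground its answer in it.

`ragvar` implements such a pipeline end to end, *and* the machinery needed to
measure whether grounding actually helps: a benchmark generator, a
five-criterion scoring rubric with an LLM-judge harness, and the full
statistical battery for paired multi-system comparison and inter-rater
reliability.

## The pipeline

A question is processed in six steps:

1. the user asks a free-text question (e.g. *"What is the clinical
   significance of rs34637584 in ClinVar?"*);
2. `extract_identifier()` scans it for a single dbSNP rs number or HGVS
   notation;
3. `normalize_identifier()` turns the identifier into the query the variant
   store understands — rs ids pass through untouched; genomic-level HGVS
   SNVs (`chr12:g.40340400G>A`) are parsed locally; all other HGVS notations
   are resolved to a GRCh38 allele (chromosome, 1-based position, ref, alt)
   through a pluggable *recoder* contract;
4. `fetch_variant()` retrieves the record as raw JSON from a pluggable
   variant-store client;
5. `build_rag_prompt()` substitutes that JSON, verbatim and exactly once,
   into the three-section prompt template (expert role, the six items every
   answer must cover, the retrieved record);
6. a pluggable LLM backend completes the prompt and the answer is returned
   in an envelope that records full provenance (identifier, normalized
   query, retrieved JSON, backend, timing).

Questions with no identifier — and questions whose variant is unknown to the
store — fall back to the *baseline* prompt: the same template minus the
retrieval section and minus every sentence referring to the database API.
Keeping the six content items in the baseline matters: it makes "RAG vs
no-RAG" a one-factor experiment rather than a prompt-quality confound.

All three external dependencies are contracts with deterministic fixture
implementations shipped in the package (`fixture_recoder()`,
`mock_variant_client()`, `stub_llm_backend()`), so the entire chain runs
offline and byte-reproducibly. The stub backend is not a language model and
does not pretend to be: it renders the six items directly from the retrieved
JSON (or states that there are no data), which is exactly what end-to-end
tests need to assert on content.

```{r pipeline}
client <- mock_variant_client(system.file("extdata", "variants",
                                          package = "ragvar"))
env <- answer_question("What is the clinical significance of rs34637584 in ClinVar?",
                       client = client, llm = stub_llm_backend())
cat(env$answer_text)
```

## The variant record

The record schema (`inst/extdata/variant_record.schema.json`) mirrors the
field roster of the public integrated variant database the pipeline targets:
database id, rs id, GRCh38 coordinates and alleles, gene symbol, clinical
significance with conditions, most severe Sequence Ontology consequence,
protein/cDNA/genomic HGVS, SIFT/PolyPhen/AlphaMissense predictions (scores
constrained to [0, 1]), per-dataset allele frequencies (constrained to
[0, 1]; dataset names deliberately free-form, since live services add
cohorts over time), and external links. The exact JSON layout of the live
service is not public, so the schema is an artifact-defined stand-in around
the documented field roster; `parse_record()`/`render_record()` are exact
inverses, and absent optional fields are omitted, never fabricated.

One fixture — `rs34637584`, the LRRK2 p.Gly2019Ser Parkinson-disease
variant — is transcribed field-for-field from the published annotation and
serves as the canonical worked example. All other fixtures are generated by
`generate_variant_record()`, which is deterministic per seed and emits
records whose genomic HGVS is consistent with their own coordinates.

## The benchmark

The question registry is data, not code: 50 templates in 8 categories, each
containing the `{rs}` placeholder, stored as a TSV resource.
`build_pool()` instantiates every template with every variant of a
user-supplied rs list — 50 × 30 = 1500 questions with the shipped 30-id
list — in deterministic template-major order. `sample_constrained()` draws
the n = 150 evaluation subset under the constraint that every template
appears at least once: one uniform question per template, then the remainder
uniformly without replacement. This sampler is a design choice (only the
constraint itself is externally fixed); it is simple, gives every question
positive inclusion probability, and is reproducible by seed.

The packaged rs list is a *synthetic stand-in* (the original 30 variants are
not public as a list); it exists so that all counts reproduce, and any real
analysis should supply its own list.

## Scoring and winner tallies

Answers are scored 0–10 on five criteria — accuracy, completeness, logical
consistency, clarity/conciseness, evidence support — and the total is their
sum (0–50). Raw rater scores are integers; the primary analysis uses the
mean of two raters per criterion, so half-integers arise and are kept exact.
`winner_tally()` credits a system for a question only on a *strict* unique
maximum of the total score; shared maxima are ties attributed to no system.
Percentages round half-up to one decimal (135/150 → 90.0), matching the
conventional rendering; rounding never happens before the strict-max test.

`llm_judge()` runs the same rubric through any backend: it demands a strict
JSON block with one integer per criterion and refuses (never clamps)
out-of-range or unparsable output, keeping the raw judge text for audit. The
shipped rubric restates the criterion definitions; it is a package-authored
stand-in for the unpublished production judging prompt. Whether a judge
scores in one pass or several is configurable by simply calling it
repeatedly; the default is a single pass.

## The statistical battery

* **`bootstrap_ci()`** — percentile bootstrap of the mean, default 10⁴
  resamples, resampling questions (the pairing unit). The resampling unit is
  a design choice; resampling (question, rater) pairs would mix reliability
  into the sampling distribution.
* **`friedman_w()`** — within-question mid-ranks with the standard tie
  correction; Kendall's W is reported through the identity
  χ² = n(k−1)W, so W = 1 iff every question ranks the systems identically.
  An all-constant-rows matrix has no rank information and raises a classed
  error rather than returning NaN.
* **`wilcoxon_holm()`** — all k(k−1)/2 paired signed-rank tests. Zero
  differences are dropped (Wilcoxon's rule; Pratt's rule available via
  `zero_method = "pratt"`). The exact distribution is used for ≤ 25 nonzero
  pairs — with ties the exact distribution does not exist and the
  normal approximation with continuity correction is used, as in standard
  implementations. Holm is applied over the pair family within each call;
  an all-zero pair is reported as p = 1 with a `degenerate` flag. Median
  paired differences are computed over *all* questions, zeros included.
* **`icc_2_2()`** — two-way random effects, absolute agreement, average
  measures, from the ANOVA mean squares:
  ICC = (MS_R − MS_E) / (MS_R + (MS_C − MS_E)/n). It may legitimately be
  negative; the zero-variance degeneracies raise classed errors.
* **`weighted_kappa()`** — quadratic weights w_ij = 1 − (i−j)²/(K−1)² over
  the 51 ordinal total-score categories 0–50; half-integer rater means are
  doubled to a 0–100 grid rather than rounded, so no information is
  destroyed before binning.

Every one of these is tested against an independent oracle computed by a
different route (textbook rank-sum implementation, exhaustive sign-assignment
enumeration, two-way `aov` decomposition, hand-worked 3-category kappa
table). The published evaluation tables themselves are *not* reproducible
here — the underlying human and model rating data are not public — so the
tests verify the statistics, not the study's numbers.

## The score simulator and what a green test establishes

`simulate_scores()` generates two-rater long-format score tables with known
ground truth: per (question, system, criterion) a latent quality
N(μ_sc, s²), observed by each rater with independent N(0, σ²) noise,
rounded to integers and clipped to 0–10. Defaults (s = 1.5, σ = 1) give
realistic rater behavior: mostly 1-point criterion disagreements,
occasional larger ones.

Under this model the closed-form reliability of two-rater mean totals is

ICC(2,2) = s² / (s² + (σ² + 1/12)/2),

where 1/12 is the variance added by integer rounding. The parameter-recovery
test fixes s = 2, σ = 1.5, mean quality 5 (mid-scale, so clipping at 0/10 is
negligible) and checks that this closed form lies within the percentile band
of replicate recoveries at n = 500. These parameters were chosen a priori
from the model, not tuned to the observed recovery.

What the simulator deliberately does **not** emulate: real LLM answer text,
criterion–criterion correlation within an answer, rater severity drift over
a session, and question-difficulty × system interactions. A green
recovery test therefore establishes that the statistics estimate what they
claim on data matching their assumptions — not that any particular system
comparison in the wild will behave this way.

## Numerical and degenerate-input policy

* All randomized operations take explicit seeds and restore the caller's RNG
  state (`withr::with_seed`).
* Strict-max winner comparison uses exact floating-point equality on scores
  that are integers or exact halves — safe by construction, never re-rounded.
* Percentages round half-up (not banker's rounding) to one decimal.
* Classed conditions (`ragvar_*_error`) distinguish ambiguity, parse,
  validation, unresolvable-identifier, retrieval, judging, infeasibility and
  undefined-statistic failures; pipeline errors carry their stage
  (extract/recode/fetch/complete).
* "Variant not found" is a normal outcome (baseline path, miss recorded),
  distinct from a transport error, which raises.

## Known limitations

* The local HGVS grammar covers genomic-level SNV substitutions only;
  everything else requires a recoder table (the live recoding service is out
  of scope by design — the shipped recoder is a lookup table).
* Only single-variant questions are supported; two distinct identifiers in
  one question raise an ambiguity error rather than guessing.
* The mock variant store is a fixture directory, not an HTTP service;
  structural variants are not modeled.
* `answer_batch()` honors a concurrency argument via forked workers, but
  order preservation — not scheduling — is the contract; with the stub
  backend serial execution is already byte-deterministic.
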