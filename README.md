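# ragvar

Retrieval-augmented interpretation of human genomic variants, plus the
benchmark and statistics needed to prove it helps.

## What this is for

Clinicians, genetic counselors and bioinformaticians increasingly ask
language models free-text questions about variants ("Is rs671 associated
with any diseases?"). Unconstrained models hallucinate: wrong genes, wrong
frequencies, invented clinical significance. `ragvar` implements the
standard remedy — retrieval-augmented generation (RAG) against a curated
variant database — as a fully pluggable pipeline, and pairs it with an
evaluation harness for deciding, quantitatively, whether a grounded system
beats an ungrounded one.

The pipeline: extract the single rs number or HGVS notation from the
question → normalize it to an rs query or a GRCh38 genomic allele
(chromosome, 1-based position, ref, alt) → fetch the variant's integrated
annotation (allele frequencies, ClinVar-style clinical significance,
SIFT/PolyPhen/AlphaMissense predictions) as JSON → substitute that JSON
verbatim into a three-section prompt → complete with any LLM backend.
Questions without an identifier, or about unknown variants, get the same
prompt minus the retrieval section, so RAG is the only manipulated factor.

The evaluation half scores answers on five 0–10 criteria (accuracy,
completeness, logical consistency, clarity/conciseness, evidence support;
total 0–50), tallies per-question strict-max winners with ties credited to
no one, and runs the comparison statistics:

- per-system means with percentile **bootstrap CIs** (resampling questions);
- **Friedman test** paired within questions, with **Kendall's W** via
  χ² = n(k−1)W;
- pairwise **Wilcoxon signed-rank** tests with **Holm** adjustment;
- inter-rater reliability: **ICC(2,2)** (two-way random effects, absolute
  agreement, average measures), **quadratic-weighted Cohen's κ** on 0–50
  totals, and absolute rater-difference summaries.

Everything external — HGVS recoder, variant store, LLM — is a contract with
a deterministic fixture implementation, so the whole package runs offline.

## Worked example

The packaged fixture `rs34637584` (LRRK2 p.Gly2019Ser, the classic autosomal
dominant Parkinson disease 8 variant) is the canonical record:

```r
library(ragvar)

client <- mock_variant_client(system.file("extdata", "variants", package = "ragvar"))
env <- answer_question("What is the clinical significance of rs34637584 in ClinVar?",
                       client = client, llm = stub_llm_backend())
cat(env$answer_text)
```

```
Answer to: What is the clinical significance of rs34637584 in ClinVar?

1. Variant identification: rs34637584 (tgv45580587), chr12:40340400 G>A, gene LRRK2, ENST00000298910.12:c.6055G>A
2. Disease associations: Autosomal dominant Parkinson disease 8 (pathogenic, likely pathogenic); predictions: SIFT 0 (deleterious), PolyPhen 1 (probably damaging), AlphaMissense 0.936 (likely pathogenic)
3. Literature evidence: There are no data available for this item.
4. Allele frequency comparison: ToMMo 0.000028, gnomAD Genomes 0.00036, gnomAD Exomes 0.00041, GEM-J WGA 0.000065, NCBN 0.00012
5. GWAS findings: There are no data available for this item.
6. TogoVar link: https://grch38.togovar.org/variant/tgv45580587
```

The stub backend is not a model — it deterministically renders the six
required answer items straight from the retrieved JSON (stating "no data"
where the record is silent), which is what makes end-to-end content
assertions possible. Swap in a real model with
`llm_backend(function(bundle) ..., name = "my-model")`.

Benchmark construction and a winner tally on simulated ratings:

```r
pool <- build_pool(load_templates(), default_rs_list())   # 50 x 30 = 1500 questions
sampled <- sample_constrained(pool, 150, seed = 1)        # every template >= once

cfg <- score_sim_config(60, list(rag = 8.5, llm_only = 4.5, variant_tool = 6),
                        rater_noise_sd = 1, between_sd = 1.5, seed = 1)
scores <- simulate_scores(cfg)                            # 2 raters x 3 systems x 60 questions
tot <- totals_matrix(mean_rater_scores(scores))
winner_tally(tot)
```

```
Winner tally over 60 questions:
  llm_only                 0 (0.0%)
  rag                     60 (100.0%)
  variant_tool             0 (0.0%)
  tie (no unique winner)     0 (0.0%)
```

`compare_systems(mean_rater_scores(scores))` adds bootstrap CIs,
Friedman/W and Holm-adjusted Wilcoxon pairs per criterion;
`agreement_report(r1, r2)` gives ICC(2,2), weighted κ and rater-difference
summaries. A command-line front end covering ask/batch/pool/sample/
fixtures/simulate-scores/tally/compare/agreement ships at
`inst/cli/ragvar-cli.R`.

## Package layout

- `R/identifiers.R` — rs/HGVS extraction, GRCh38 allele, local genomic-SNV
  parser, recoder contract
- `R/variant-store.R` — variant record model, JSON round-trip, mock client
  with call log
- `R/prompting.R` — three-section template, RAG and baseline prompt builders
- `R/rag-pipeline.R` — orchestration, batching, backend contract
- `R/benchmark.R` — template registry, pool, constrained sampling
- `R/evaluation.R` — rubric scores, rater aggregation, winner tally, LLM judge
- `R/stat-battery.R` — bootstrap, Friedman/W, Wilcoxon–Holm, ICC, κ
- `R/synthetic-data.R` — record generator, score simulator, stub backends
- `vignettes/variant-rag-evaluation.Rmd` — models, assumptions, design
  decisions, limitations
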