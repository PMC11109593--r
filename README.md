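# trialminer

Automated evidence synthesis for behaviour change: **trialminer** re-builds,
at desk scale, an information-extraction and outcome-prediction system for
reports of randomised controlled trials (RCTs) of smoking-cessation
interventions. It is aimed at researchers in text mining for systematic
reviews and at behavioural scientists who want a fully seeded, inspectable
pipeline from raw trial text to per-arm outcome predictions.

## What it does

A trial report is reduced to a structured record in three stages:

1. **Entity extraction.** A 70-entity schema (behaviour change techniques,
   delivery modes, population descriptors, abstinence outcomes; shipped in
   `inst/extdata/synthetic_smoking_cessation_schema.csv`, a constructed
   stand-in list, not a published one) defines the targets. Entities
   are of three kinds: *presence-absence* (e.g. "goal setting" was used),
   *value* (e.g. mean age = 44.5), and *complex components* (e.g. ethnic-group
   percentages under a parent class). Sentences — and **pseudo-sentences**
   linearized from tables, one per data cell — are tokenized and labelled with
   the BIO scheme (`B-x`/`I-x`/`O`). Two tagger families share one contract: a
   deterministic gazetteer (longest-match over training mention surfaces) and
   a trainable feature-count model decoded by a Viterbi search whose
   transition constraints enforce BIO validity.

2. **Arm resolution.** The number of arms *n* is read from the conventional
   "randomised into/in *n* groups" phrase. Arm-name mentions are grouped by
   complete-link agglomerative clustering (cluster similarity = the Jaccard
   similarity of the two most dissimilar members) into *n* clusters, each
   labelled by its most frequent member. Every entity mention is then
   attached to the arm of the nearest arm-name mention within a window of
   *t* tokens (default 30), else to the whole study.

3. **Outcome prediction.** From *gold* annotations (never tagger output, so
   extraction error cannot confound the comparison), each arm with an
   abstinence outcome y (0–100%) becomes a feature vector. Four models are
   compared by k-fold cross-validated RMSE: the grand mean; an additive
   linear model fit by minimum-norm least squares; and a stacked-LSTM
   regressor reading the schema-ordered entity sequence, each entity
   represented by its co-occurrence-graph embedding (node2vec-style biased
   random walks + skip-gram) scaled by the entity's presence/value, optionally
   concatenated with corpus-trained context-text embeddings.

Evaluation utilities cover per-entity precision/recall/F1 (Table-style
summaries), a two-coder human benchmark, nominal Krippendorff's alpha, and
seeded cross-validation folds. A synthetic-corpus generator emits gold
trial reports with known arms, entity values, tables and a known linear
outcome model `y = b0 + sum(beta * presence) + sum(gamma * numeric) + e`,
so every stage is testable without any external data.

## Worked example

```r
library(trialminer)

cfg    <- generator_config(seed = 7, n_docs = 40, synonyms = TRUE)
corpus <- generate_corpus(cfg)                       # gold-annotated reports
seqs   <- unlist(lapply(corpus, study_tag_sequences), recursive = FALSE)
tagger <- train_tagger(seqs, tagger_config(family = "statistical", seed = 7))
res    <- run_extraction(lapply(corpus, function(s) s$doc), tagger,
                         generator_schema(), arm_config(window = 30),
                         gold = corpus)
print(res$report)
cat(sprintf("arm-assignment accuracy: %.3f (n = %d)\n",
            res$arm_accuracy$accuracy, res$arm_accuracy$n))
rep <- run_prediction_experiment(corpus, generator_schema(), k = 5, seed = 7)
print(rep)
```

Output:

```
Extraction evaluation (per-entity F1 summary)
  mean     F1 1.00
  median   F1 1.00
  maximum  F1 1.00
  minimum  F1 1.00
  (10 entities scored)
arm-assignment accuracy: 1.000 (n = 505)
Outcome prediction, 5-fold cross-validated RMSE (seed 7)
  Grand mean                           7.32
  Linear regression                    3.32
  ML algorithm, entities only          5.31
  ML algorithm, entities plus text     4.54
```

Reading it: on this clean synthetic corpus the trained tagger recovers every
entity (F1 = 1 per entity) and every entity lands on its correct arm. The
generator's outcome model is additive with noise SD 3.25, so the correctly
specified linear baseline approaches that floor (3.32), the grand mean sits
near the marginal outcome SD (7.32), and the recurrent models fall in
between. On a *zero-signal* corpus no model beats the grand mean — the
qualitative structure such systems report in practice.

## Command line

`inst/cli/trialminer` exposes `simulate`, `train-tagger`, `tag`,
`resolve-arms`, `evaluate`, `predict` and `run-all`, all JSON-lines in/out,
e.g.

```sh
Rscript inst/cli/trialminer run-all --n 100 --seed 1 --outdir results/
```

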