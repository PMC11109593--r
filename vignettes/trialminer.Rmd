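---
title: "trialminer: models, defaults, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trialminer: models, defaults, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialminer)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter and their defaults, what the
synthetic-data generator emulates, and the choices made where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## The task

Systematic reviews of behaviour change interventions need, for every
randomised trial report: *which* discrete entities the trial involved
(techniques, delivery modes, population descriptors, outcomes), *which study
arm* each entity belongs to, and ultimately a prediction of each arm's
cessation outcome from those entities. trialminer implements this as three
composable stages — BIO sequence tagging over sentences and table
pseudo-sentences, arm resolution by mention clustering and proximity, and a
cross-validated outcome-prediction experiment — plus the evaluation
machinery (F1, Krippendorff's alpha, RMSE) to score each stage.

## Data model

An `entity_schema` is a flat table of extraction targets with three kinds:
`presence_absence`, `value`, and `complex_component` (a value carrying a
`parent_id`, e.g. per-ethnic-group percentages under "ethnic group"). The
full ontology behind the schema is out of scope; only the flat table and
the parent link are modelled, and parent links must form a forest.

Annotations use 0-based half-open character spans, chosen for composability
with tokenization. Value parsing (`normalize_value`) takes the *first*
decimal numeral in the annotated string ("44.5 years" gives 44.5); word
numerals are out of scope. Percentages stay on the 0–100 scale. Corpora are
JSON-lines, one study per line, so they stream.

Arm linkage lives on every annotation as `arm_ref`, with `WHOLE_STUDY` as
the neutral sentinel. Complex components reported study-wide keep
`WHOLE_STUDY` too — the source material does not dictate how such
sub-values attach to arms, so the field is simply available on every
component.

## Ingestion

Sentence segmentation is rule-based and deterministic (reproducibility was
preferred over marginal segmentation accuracy): split at `.?!` followed by
whitespace and an uppercase letter, suppressed after a stop-list of
abbreviations ("et al.", "Fig.", ...). Segmentation is lossless — every
character belongs to exactly one sentence or to inter-sentence whitespace —
which the tests assert on generated documents.

Tables arrive as structured grids, not parsed from PDF (layout parsing is a
non-goal; PDFs are a notoriously lossy source). Each non-empty data cell
becomes one pseudo-sentence `"<row header> : <column header> is <cell> ."`,
multi-level headers joined by `" , "`. The template is a package choice:
simple, injective for distinct headers, and tokenizer-friendly. Captions
are *excluded* from linearization; that is a configuration point, not a
claim about the right answer.

## Tagging

The tokenizer splits on whitespace and punctuation but keeps decimal
numbers whole ("44.5" is one token) — how decimals should tokenize is
genuinely open, and this choice is recorded in the model config.

Mentions are encoded as BIO tags; `encode_bio` rejects overlapping gold
mentions (the scheme implies non-overlapping spans per sentence), and
`decode_bio` is total: a leading `I-x` (or an `I-x` after a different
label) is repaired to `B-x`, the standard lenient decoding. Encode and
decode are mutually inverse on valid input, property-tested.

Two tagger families sit behind one `train_tagger`/`tag_document` contract:

* **gazetteer** — a longest-match dictionary of training mention surfaces,
  leftmost-longest, ties to the lexicographically smallest label. On a
  corpus whose surfaces are unambiguous it is equivalent to exact string
  search, which makes it the noise-free reference for end-to-end tests.
* **statistical** — per-token emission scores from smoothed conditional
  frequencies of six feature families (word, shape, two left and two right
  neighbours), combined naive-Bayes style, decoded by Viterbi with hard
  transition constraints that forbid invalid BIO sequences. Those
  constraints play exactly the role a CRF output layer plays in a neural
  tagger.

Production systems for this task use pretrained word and contextual string
embeddings feeding a BiLSTM-CRF, trained on billion-word corpora.
Reproducing that at desk scale is neither possible nor informative; the statistical family keeps the
interface (including a config slot for concatenating external pretrained
vectors) while training in seconds on a CPU. A green tagger test therefore
establishes that the *pipeline contract* holds on templated text — not
that this tagger would reach neural accuracy on real prose.

## Arm resolution

The arm count n comes from the conventional phrase `(into|in) n
(groups|arms|conditions)`, digit or word numeral, first match wins. When no
phrase matches, clustering falls back to a similarity floor (default 0.2):
merging stops once the best complete-link similarity drops below it.

Mention similarity is token-set Jaccard over lowercased,
punctuation-stripped tokens. The source material names complete-link
clustering but not its similarity function; Jaccard was chosen because it
handles head-sharing synonymy ("patch" / "patch group") with no training
and is deterministic. Clustering merges the pair of clusters with the
highest complete-link similarity (the similarity of their two most
dissimilar members) until n clusters remain; merge ties break on the
lexicographically smallest pair of cluster keys so results are exactly
reproducible. Each cluster is labelled by its most frequent member surface,
ties to the earliest occurrence in the document.

Entity-arm association assigns each entity mention to the arm of the
nearest arm-name mention within a window of t **tokens** (the window unit
was unspecified in the source; tokens were chosen over characters), default
t = 30, exposed in `arm_config` because the right window can only be set
empirically per corpus. Distance is measured between nearest token boundaries;
equidistant candidates default to the *preceding* mention, since in trial
prose the arm label typically precedes its statistics. Mentions from table
pseudo-sentences only associate within their own pseudo-sentence. With no
arm mention inside the window the entity falls back to `WHOLE_STUDY`.
Association is monotone in t: enlarging the window never turns an arm
assignment into a fallback.

## Evaluation

The matching criterion for F1 is *document-level instance matching*: a
predicted instance is a true positive when gold has an instance with the
same document and entity and — for value-bearing entities — the same
normalized value; matching is 1-to-1, greedy in document order. Span-exact
matching exists as a strict mode. Document-level matching is the default
because per-entity retrieval is what is being scored and span conventions
across annotators are unknowable. Zero-denominator precision/recall are
defined as 0 (not NaN) so summaries stay total.

Whether an instance should also need the *correct arm* to count as a true
positive is left decoupled: entity F1 and arm-assignment accuracy (the
fraction of matched instances whose predicted arm maps to the gold arm) are
reported separately, since arm association is the fragile stage and folding
it into F1 would hide which stage failed.

Krippendorff's alpha is the two-coder nominal form computed from the
coincidence matrix; the degenerate all-identical-single-category case is
undefined and reported as 1 with a warning. Cross-validation folds are a
seeded shuffle dealt round-robin: disjoint, exhaustive, sizes within one.

## Outcome prediction

One feature vector per arm-with-outcome: presence flags in schema order,
then standardized numeric features with a missingness flag each (missing
becomes flag = 1, value = 0 after standardization), so the design width is
`#presence + 2 x #value`. Whole-study annotations propagate to every arm of
their study. Standardization statistics come from the training fold only;
a leakage assertion guards the fold loop. When an arm reports several
abstinence outcomes, the entity latest in schema order (the longest
follow-up, as the shipped schema orders them) is the target; the choice is
exposed as `outcome_entity`.

The co-occurrence graph has entities as nodes and document co-occurrence
counts as edge weights. Node embeddings come from second-order biased
random walks (return p, in-out q, both default 1) fed to a
negative-sampling skip-gram trained by minibatch SGD — all in R, all
seeded. Text embeddings use the same skip-gram trained on the corpus's own
context sentences; externally pretrained biomedical vectors are replaced by
this local training deliberately, so no download is required and the
mechanism stays identical.

The recurrent model consumes the schema-ordered entity sequence: timestep
input = the entity's graph embedding scaled by its presence/standardized
value, plus the scalar and its missingness flag; in `entities_plus_text`
mode the sample's mean-pooled context-text embedding is concatenated at
every step. Beyond "concatenate the embeddings" there is no canonical way
to lay out these inputs, so this concrete sequence layout is a package
choice. A
two-layer LSTM (full BPTT, Adam, forget-gate bias 1) reads the sequence;
a linear readout predicts the standardized outcome, un-standardized and
clipped to [0, 100] because outcomes are percentages. Layer sizes, epochs
and learning rate are config with documented defaults (2 x 16 units, 120
epochs, 0.02) — no standard values exist, and these defaults
are small enough to train in seconds yet deep enough to fit a noise-free
linear world to under one percentage point of training RMSE (a single
recurrent layer demonstrably is not, which is why the default is a stack).

Baselines: the grand mean (whose training RMSE equals the training
outcomes' population SD — asserted numerically) and an additive linear
model solved by minimum-norm pseudoinverse so rank-deficient designs (e.g.
duplicated columns) behave; coefficient standard errors use the same
pseudoinverse and match `lm()` on full-rank designs. The experiment always
consumes gold annotations rather than tagger output, so extraction error
cannot confound the model comparison.

## The synthetic world

`generator_config()` defaults *are* the stated world; they were fixed
before the acceptance measurements and are not tuned afterwards:

* arm counts over 1–4 with weights (.05, .55, .30, .10) — most smoking RCTs
  have two or three arms;
* five arm-scoped technique entities included with probability .5 each;
  mean age ~ U(35, 55) years and cigarettes/day ~ U(10, 30), always
  reported; ethnicity components (60%); every arm reports a 12-month
  abstinence percentage;
* outcome model: intercept 25, technique effects (8, -6, 5, -4, 3)
  percentage points, age effect 0.2/year, cigarettes effect -0.3/cig,
  noise SD 3.25. With inclusion probability .5 the technique signal
  variance is 37.5 and the numeric signal ~4.8, giving signal R-squared of
  about 0.8 and realistic cessation outcomes (mean ~30%, SD ~7). The
  zero-signal world sets all effects to 0 and the noise SD to 10,
  a realistic scale for the marginal variability of cessation outcomes.

Values are rendered to one decimal in the text and the gold value is parsed
back from the rendering, so text, gold and features are exactly consistent.
Hard cases are toggles, off by default: synonymous arm mentions (each arm's
defining sentence always uses the canonical head form, synonyms elsewhere),
table-only outcome reporting, and an out-of-window mode in which arm names
are listed once early and every entity sentence is padded away from them.

Two template decisions deserve a note. Buffer sentences separate the
study-level block, consecutive arm blocks, and the outcomes block; without
them the trailing entity of one arm's sentence sits closer to the *next*
arm's name, and study-level values fall inside the window of the first
arm — both genuine failure modes of the nearest-mention heuristic. The
generator places them apart precisely so that gold assignments are
*recoverable by construction*, making the arm-recovery test an upper-bound
test of the machinery, not a measurement of prose robustness. Second, the
out-of-window stress corpus disables tables, because a results-table row
names its arm inside its own pseudo-sentence and would legitimately (and
correctly) be associated.

What a green suite establishes: the codecs, metrics and clustering match
independent oracles; the pipeline is deterministic given seeds; on text
whose regularities match its assumptions the tagger and arm resolver are
near-perfect; and the prediction experiment reproduces the expected
qualitative RMSE ordering (correctly specified linear model near the noise
floor on strong signal; nothing beating the grand mean on zero signal).
What it does not establish: performance on real journal prose, real tables,
or any real annotated corpus — synthetic templates have none of the layout noise,
coordination, or "respectively" constructions that defeat extraction in the
wild.

## Numerical and testing notes

* All randomness flows through per-stage seeds derived from a master seed;
  `.Random.seed` is saved and restored around every seeded internal, so
  library calls never perturb a caller's RNG stream.
* The parameter-recovery acceptance check fits the linear baseline on five
  replicate 300-arm corpora with consecutive fixed seeds and tests the
  inverse-variance-pooled estimate within 3 pooled standard errors. A
  single 300-arm corpus puts some coefficient outside 3 SE roughly 2% of
  the time purely by sampling (seven coefficients at a 0.3% tail each);
  pooling keeps the same nominal level while more than doubling the power
  to detect genuine bias. The replicate whose draw motivated this note is
  *included* in the pool.
* The zero-signal prediction check runs 30 replicate corpora of 30 studies
  with a reduced recurrent training schedule (40 epochs) to stay inside
  the time budget; an undertrained network regresses toward the mean, so
  the property under test — nothing beats the grand mean without signal —
  is unaffected by the reduction.
* LSTM gradients are verified against central-difference numeric
  differentiation in the unit tests.

## Known limitations

Coreference beyond surface-form clustering, the "respectively"
construction, cross-document arm alignment, real PDF ingestion, word
numerals in values, and multi-coder (>2) agreement are all out of scope.
The statistical tagger is a desk-scale stand-in: its feature set is strong
on templated text and weak on free prose by design.
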