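---
title: "Methods: extracting and tracking ground-glass opacity findings from radiology notes"
author: "ggonlp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extracting and tracking GGO findings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggonlp)
```

## The problem

Ground-glass opacities (GGOs) are hazy pulmonary lesions on CT that do not
obscure the underlying structures. They matter clinically because persistent
GGOs — those seen across serial scans without resolving — and GGOs with
certain features (larger baseline size, part-solid composition, spiculated
margins, upper-lobe location) carry elevated malignancy risk. The findings
are documented almost exclusively in free-text radiology notes, so studying
their natural history at scale requires information extraction: recognizing
GGO mentions and their attributes in text, normalizing them to a structured
schema, and assembling per-patient timelines.

`ggonlp` implements that pipeline end to end: a GGO annotation ontology, a
synthetic note generator with known truth, corpus IO, embedding-based query
expansion, a Bi-LSTM-CRF entity tagger with rule-based relation linking,
attribute normalization, evaluation bookkeeping, and longitudinal analytics.
This vignette records the modelling choices, their defaults, and what the
package's tests do and do not establish.

## The ontology

Fifteen entity semantic types cover the two GGO mention kinds
(`pure_ggo_term`, `part_solid_ggo_term`), six attributes (size, quantity,
location, shape/margin, solidity, temporal), four potential-etiology
subtypes (neoplasm, infectious/inflammatory, hemorrhage, other pulmonary)
and three status-change directions (better, stable, worsen). Status
subtypes and etiology subtypes are distinct entity types rather than one
type with a value slot, because extraction quality is scored separately per
subtype. Seven relation types each anchor on a GGO mention and point at one
attribute family; the tail families are disjoint, so a relation's type is
fully determined by its tail entity. Relations are directed from the GGO
mention to the attribute. The temporal type deliberately has no relation:
notes state comparison dates at sentence or note scope, and no reliable
mention-level linking rule exists, so dates attach to findings by sentence
co-occurrence during normalization.

The BIO label space is `O` plus `B-`/`I-` per entity type (31 labels). BIO
rather than BIOES keeps the transition structure minimal; spans in this
domain are short noun phrases and the richer scheme adds states without
adding information.

## The synthetic corpus: what it emulates and what it does not

No radiology corpus can be shipped, so the generator is a first-class module
that emulates the *structure* of GGO reporting: a FINDINGS/IMPRESSION
scaffold, one sentence per finding built from a surface lexicon (mention,
size in mm/cm or two-dimensional form, lobe or laterality phrase, shape,
quantity concept, status phrase, comparison date, etiologies, solidity
phrase), distractor sentences without annotations, and gold standoff spans
that are exact character slices of the rendered text.

Defaults are fixed once and state the study conditions:

* **Trajectory mix** `increase 0.230 / decrease 0.024 / stable 0.723 /
  resolved 0.023` — the longitudinal status-outcome distribution reported
  for real lung-cancer cohorts (roughly 72% stable, 23% increased, ~2%
  each decreased/resolved).
* **Pregroup probability** `0.377` — the share of patients whose first GGO
  report precedes the lung-cancer diagnosis date in such cohorts.
* **Notes per patient** uniform on 1–5; trajectory classes that need two
  time points (increase, decrease, resolved) draw at least 2.
* **Attribute documentation frequencies** (location 0.85, etiology 0.50,
  shape 0.40, quantity 0.35, temporal 0.25, solidity 0.15) reflect that
  laterality/location is the most consistently documented attribute while
  shape and solidity are sporadic; they are configurable probabilities
  checked empirically by a 3-standard-error test.
* **Findings per note**: one *index* finding — the longitudinally tracked
  nodule, whose kind, location and shape are constant within a patient —
  plus, with probability 0.35, one extra finding carrying no size or status
  span. Keeping size/status on the index finding only is a deliberate
  generator property: the daily rollups (largest size, worst status) then
  recover the constructed truth exactly, which is what the truth-recovery
  tests assert. Real notes have no such guarantee.
* A resolved trajectory ends in a resolution sentence ("... has resolved")
  tagged as a `status_better` span with no size; single-note patients are
  nonpersistent unless their one note carries a worsening indication (drawn
  with probability 0.3 among single-note patients).

The generator does **not** emulate negated findings (no negation component
is modelled), section headers beyond the two-line scaffold, de-identification
artifacts, OCR noise, tracking ambiguity between multiple nodules, or
free-form narrative variation beyond the lexicon. Consequently, a high
held-out F1 on synthetic notes demonstrates that the architecture, training
loop, decoding and bookkeeping are correct — not that the tagger would reach
the same accuracy on hospital text, whose vocabulary and syntax are far
richer. Conversely, the metric worked examples test the evaluation
arithmetic against published count triples independently of any corpus.

Determinism: a configuration plus seed yields a byte-identical corpus and
truth tables; the generator saves and restores the caller's RNG state.

## Tokenization

Sentences split on newlines and on periods followed by whitespace (a period
between digits, as in "1.2 cm", never splits). Tokens are letter runs,
numbers with an optional decimal part, or single punctuation characters, so
"3mm" becomes "3", "mm". Every token carries exact 0-based half-open
character offsets over code points, making span decoding lossless. For
embedding training, tokens are lowercased and punctuation is dropped; for
the tagger, purely numeric tokens additionally collapse to a `<num>` class
so size values generalize across numbers.

## Query expansion

Bigram detection scores adjacent pairs by
`(count(ab) − min_count) · N / (count(a) · count(b))` with `N` the total
token count of the corpus, and merges scoring pairs in a single greedy
left-to-right pass (so "b b b" becomes "b_b", "b"). Embeddings are
skip-gram with negative sampling: dynamic window, unigram^0.75 noise
distribution, linearly decaying learning rate, single-threaded with an
internal 64-bit RNG so training is bit-for-bit reproducible. Defaults
(window 5, dimension 100, min_count 5, 5 epochs, 5 negatives) are the
conventional word2vec settings; none is prescribed by the task. Term
expansion returns ranked candidates only — accepting expanded terms is a
human curation step by design.

## The tagger

Architecture: word embeddings (default 24 dimensions) feed a bidirectional
LSTM (24 units per direction); the concatenated hidden states map linearly
to 31 emission scores per token; a linear-chain CRF with learned transition
matrix (including start/stop states) defines the sequence distribution.
Training minimizes the exact negative log-likelihood — `log Z` from the
forward algorithm in log space minus the gold path score — with gradients
from forward–backward marginals, full backpropagation through time, and
Adam (learning rate 1e-3, batch 16 sentences, β₁ 0.9, β₂ 0.999). Word-level
embeddings suffice here: the synthetic vocabulary is closed and numerals are
collapsed, so a per-token character encoder would add training cost without
changing what the tests can demonstrate; the emission encoder is the natural
extension point if one is needed for real text.

Notes are split 80/20 into training and validation by a seeded shuffle
(by note by default; a by-patient option exists for leakage-safe
experiments). After each epoch the validation macro-F1 (exact span + type)
is recorded; the best checkpoint is kept and training stops after 5 epochs
without improvement. Everything — split, initialization (Gaussian, sd 0.1),
shuffling, C++ updates — is driven by the one seed, so training is
reproducible bit-for-bit single-threaded.

Decoding applies a BIO-legality mask at Viterbi time: transitions into
`I-x` from anything but `B-x`/`I-x` get −∞. Training is unconstrained (the
likelihood itself teaches transitions); masking only at decode time keeps
the loss smooth while guaranteeing well-formed output. Viterbi ties break
toward the lowest label index at each backtracking step, making decoding
deterministic even on degenerate score ties. A bare `I-x` from the lenient
span decoder opens a new span rather than being dropped.

Scale guidance, as used by the package's own tests: the default
configuration is tuned for corpora of several hundred notes (a ~900-note
corpus trains to macro-F1 > 0.95 in under a minute on one CPU). Small
corpora provide few Adam steps per epoch, so the small-corpus tests use
smaller batches (4–8), a slightly larger learning rate (2–3e-3) and more
epochs; these are exposed arguments, not changed defaults.

Relation extraction is deterministic nearest-anchor linking: each attribute
entity links to the closest GGO mention in the same sentence by character
gap, ties going to the preceding anchor; attributes without a same-sentence
anchor stay unlinked. The linking function is a seam where a learned
classifier could be substituted, but the rule is reproducible and matches
the anchor-attribute semantics of the ontology.

## Normalization

* **Size**: numbers with mm/cm (or spelled-out) units convert to
  millimetres; for two-dimensional "8 x 5 mm" measurements the larger
  dimension is kept; decimal commas are accepted. Unparseable surfaces
  leave `size_mm` unset rather than guessing.
* **Size bins**: `<6 mm`, `6–20 mm`, `>20 mm`. Both 6 and 20 fall in the
  middle bin — the single reading consistent with the bin labels ("6 to 20"
  inclusive against strict `<6` and `>20`).
* **Location**: two levels — laterality (right/left/bilateral) and lobe
  (RUL/RML/RLL/LUL/LLL) — from a keyword/abbreviation lexicon; "lingula"
  maps to (left, unknown); unmatched surfaces give (unknown, unknown),
  never an error.
* **Etiology**: infectious/inflammatory ← `cause_infectious_inflammatory`;
  malignant ← `cause_neoplasm`; other ← hemorrhage and other pulmonary
  lesions (fibrosis, scarring). Precancerous conditions — atypical
  adenomatous hyperplasia, adenocarcinoma in situ — are malignant by
  surface-form override regardless of the entity subtype.
* **Quantity**: "numerous", "scattered", "several", "multiple" and integers
  ≥ 2 are `multiple`; "single", "solitary", "one", 1 are `single`.
* **Status**: better/stable/worsen from the entity subtype, except that a
  `status_better` span matching a resolution surface ("resolved", "no
  longer seen", ...) becomes the terminal status `resolved`, which the
  longitudinal stage treats separately from improvement. The resolution
  lexicon is explicit and editable; it is a package choice, not a claim
  about any particular institution's phrasing.
* **Temporal**: ISO, US numeric and written dates; two-digit years resolve
  to the century nearest the note date; relative expressions ("last year")
  are unsupported and yield `NA` with a warning.

Normalizers are pure functions; `assemble_findings()` produces one finding
per GGO mention (sorted by span start) with attributes pulled through the
linked relations, and attaches a same-sentence comparison date when present.

## Evaluation

Counts are pooled over notes per semantic type: `right` (true positives
under greedy one-to-one matching in document order), `predict`, `gold`.
Precision = right/predict (0 when predict = 0), recall = right/gold (0 when
gold = 0), F1 = harmonic mean computed from *unrounded* precision and
recall; display rounding is half-up to two decimals. This combination
reproduces the published worked examples exactly (e.g. 510/535/572 →
0.95/0.89/0.92; 144/151/144 → 0.95/1/0.98). Exact span + type matching is
the default; an overlap mode exists because published evaluations often do
not state their criterion. In exact mode greedy matching attains the
optimal one-to-one matching count (spans are either identical or not), which
the tests verify against a multiset-intersection oracle. The macro rows
average per-type metrics over types present in gold or predictions.

## Longitudinal analytics

"First note" and "last note" mean the earliest/latest report *dates* with a
GGO finding; multiple notes on one day are merged by the daily rollups
before any comparison — the largest size, and the most severe status with
order worsen (increased) > stable > better (decreased). `resolved` is
terminal: a day reports it only when it is the sole status that day. The
package treats "worsen" ≡ "increased" and "better" ≡ "decreased" as one
vocabulary.

* **Persistence**: persistent iff the patient has ≥ 2 report dates and the
  last date carries no resolved finding, or exactly one report date with a
  worsening indication (worsen status or a solidity surface describing
  increase/new solid component).
* **Size change** compares first vs last rolled-up size among dates with a
  size (≥ 2 such dates required; the tolerance τ for "unchanged" defaults
  to 0 and is configurable, since no tolerance is prescribed anywhere).
* **Status outcome** summarizes the dates after the first: `increased` if
  any subsequent daily status is worsen, else `resolved` if the final
  status is resolved, else `decreased` if any is better, else `stable`.
  The inclusion threshold is ≥ 2 report dates by default and configurable,
  because stated inclusion rules differ between "at least 2" and "more
  than 2" depending on the analysis.
* **Pregroup**: first GGO report strictly before the diagnosis date;
  same-day reports count as post-diagnosis.
* **Interval bins** use day counts — < 183, [183, 366), [366, 1096), ≥ 1096
  — as the documented convention for "6 months", "1 year", "3 years";
  half-open on the right, so the bins partition all non-negative intervals.
* **Exclusive baseline size group**: the single bin shared by all sized
  first-date findings, `more_than_1` when they span bins, unset when no
  size was documented (the three cases feed different summary rows).

`cohort_summary()` assembles the patient-level tables (first-note attribute
distributions, size-change and status-outcome distributions, persistence,
pregroup interval table, and first-10-note status transition counts for a
Sankey-style plot), with percentages over each block's own denominator at
one decimal.

## Numerical choices

All CRF computations run in log space; −∞ is a legal masked score and
log-sum-exp guards against it, while `NaN` inputs are rejected loudly.
Parameters initialize from Gaussians (sd 0.1) with zero biases and zero
transitions; Adam uses bias correction from step 1; gradients average over
the minibatch. The word2vec trainer uses its own splitmix64 RNG so R's RNG
state never leaks into (or is perturbed by) C++ training. Degenerate inputs
are defined rather than accidental: empty text tokenizes to an empty list,
an empty entity table links no relations, a single-position CRF reduces to
an emission argmax, and an all-masked decode is an error.

## Problem sizes used by the tests

The test suite trains the full tagger once on a ~900-note corpus (the
acceptance condition), plus several small models (26–200 notes) for
memorization, determinism and pipeline checks; the CRF is verified against
brute-force enumeration on 1000+ random instances up to length 4 × 4
labels; property tests sweep a 0.1-mm grid for size bins and days 0–5000
for interval bins. The whole suite runs in about two minutes on one CPU,
and `scripts/acceptance.R` in about one.

## Known limitations

Negation and hedging are not modelled; findings asserted as absent would be
extracted as present. Individual nodules are not tracked across reports —
rollups operate at the patient-day level, so multi-nodule patients mix
lesions. The relation linker is a heuristic; cross-sentence attribute
references are never linked. The synthetic lexicon is small and unambiguous
by construction, so reported synthetic-corpus accuracy is an upper bound on
real-world performance. Solidity surfaces are carried as raw text rather
than normalized concepts, except for the worsening heuristic used by the
persistence rule.
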