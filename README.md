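# ggonlp

Radiology notes are where ground-glass opacities (GGOs) — hazy pulmonary
lesions on CT that may precede lung cancer — are actually documented, but the
information sits in free text. `ggonlp` is an R package for clinical-NLP
researchers and real-world-data teams that extracts GGO findings and their
granular attributes from note text, normalizes them into analysis-ready
records, scores extraction quality against gold annotations, and computes
patient-level longitudinal GGO trajectories (persistence, size change, status
change, pre-diagnosis intervals).

## What is in the box

* **Ontology** — a machine-readable annotation schema with 15 entity semantic
  types (pure/part-solid GGO mentions, size, quantity, location, shape/margin,
  solidity, temporal, four etiology subtypes, three status-change types) and
  7 relation types, each anchored on a GGO mention
  (`ggo_schema()`, `validate_relation()`, `bio_label_space()`).
* **Synthetic corpus generator** — radiology-note text with span-exact gold
  standoff annotations and multi-note patient timelines with known latent
  trajectories, so the whole pipeline is testable without any EHR access
  (`generator_config()`, `generate_cohort()`, `render_note()`).
* **Corpus IO** — BRAT standoff (`.txt`/`.ann`) and JSONL readers/writers with
  strict offset validation (`read_brat()`, `write_notes_jsonl()`, ...).
* **Query expansion** — bigram collocation detection and from-scratch
  skip-gram word2vec with negative sampling for expanding a GGO seed-term
  list (`detect_bigrams()`, `train_embeddings()`, `expand_terms()`).
* **The tagger** — a Bi-LSTM with a linear-chain CRF output layer over the
  31-label BIO space, trained by exact sequence log-likelihood. The CRF core
  (forward algorithm, Viterbi with deterministic tie-breaking,
  forward–backward gradients) and the LSTM backpropagation are implemented in
  Rcpp/RcppArmadillo; no deep-learning framework is required. Deterministic
  rule-based relation linking attaches attributes to their nearest
  same-sentence GGO anchor (`ggo_tagger()`, `predict_entities()`,
  `link_relations()`, `crf_log_partition()`, `viterbi_decode()`).
* **Normalization** — size to millimetres with the clinical `<6`, `6–20`,
  `>20` mm bins, two-level location (laterality + lobe), etiology triage
  (infectious/inflammatory, malignant — including precancerous conditions —
  and other), quantity, status with terminal resolution, and temporal
  normalization (`normalize_size()`, `assemble_findings()`, ...).
* **Evaluation** — right/predict/gold bookkeeping per semantic type with
  precision = right/predict, recall = right/gold and F1 their harmonic mean,
  computed from unrounded values (`score()`, `metrics_from_counts()`).
* **Longitudinal analytics** — persistence classification, same-day rollups
  (largest size; worst status with worsen > stable > better), first-vs-last
  size change, status trajectories, pregroup stratification, interval bins
  and cohort summary tables (`build_timelines()`, `status_trajectory()`,
  `cohort_summary()`).

The core model is the sequence labeler: for tokens `x_1..x_T` the network
produces emission scores `e_t(y)` and the CRF defines

```
P(y | x) = exp( Σ_t e_t(y_t) + Σ_t A[y_{t-1}, y_t] ) / Z(x)
```

with transition matrix `A` (including start/stop states) and partition
function `Z(x)` computed exactly by the forward algorithm; decoding is
Viterbi under a BIO-legality mask.

## Worked example

```r
library(ggonlp)

cfg    <- generator_config(n_patients = 40, seed = 21)
cohort <- generate_cohort(cfg)           # 110 annotated notes + latent truth
model  <- ggo_tagger(cohort$corpus, epochs = 25, batch_size = 8,
                     lr = 2e-3, seed = 21)
model
#> Bi-LSTM-CRF GGO entity tagger
#>   vocabulary: 124 tokens; labels: 31; emb 24, hidden 24
#>   trained on 88 notes, validated on 22 (split by note, seed 21)
#>   best validation macro-F1 0.862 at epoch 13

predict_entities(model,
  "There is a 4 mm spiculated ground-glass opacity in the left upper lobe, unchanged.")
#>   start end             type              surface
#> 1    11  15         ggo_size                 4 mm
#> 2    16  26 ggo_shape_margin           spiculated
#> 3    27  47    pure_ggo_term ground-glass opacity
#> 4    55  70     ggo_location      left upper lobe
#> 5    72  81    status_stable            unchanged
```

The entity spans are 0-based half-open character offsets; each attribute is
then linked to its GGO anchor and normalized (here: 4 mm → size bin `lt6`,
left upper lobe → laterality `left`, lobe `LUL`, `unchanged` → status
`stable`). Scoring the tagger's annotations against the gold standard pools
right/predict/gold counts per semantic type:

```r
sc <- score(predict(model, cohort$corpus), cohort$corpus)
sc[sc$semantic_type %in% c("pure_ggo_term", "ggo_size", "micro", "macro"), ]
#>  semantic_type right predict gold precision recall   f1
#>  pure_ggo_term   117     117  117      1.00   1.00 1.00
#>       ggo_size   108     108  108      1.00   1.00 1.00
#>          micro   640     647  647      0.99   0.99 0.99
#>          macro    NA      NA   NA      0.85   0.86 0.86
```

Normalized findings feed the longitudinal stage; on this small demo cohort:

```r
f    <- findings_from_notes(cohort$corpus)   # gold-entity findings
tls  <- build_timelines(f, cohort$truth$patients)
summ <- cohort_summary(tls)
summ$persistence
#>        category  n pct
#> 1    persistent 36  90
#> 2 nonpersistent  4  10
summ$size_change
#>   category  n  pct
#> 1 increase 13 37.1
#> 2 decrease  0  0.0
#> 3   stable 22 62.9
```

`increase` here means the last rolled-up daily size exceeds the first
(largest size per day when several are reported); patients with a size on
fewer than two dates are excluded from the denominator.

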