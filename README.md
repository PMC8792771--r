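# edssnlp

Extracting and predicting the **Expanded Disability Status Scale (EDSS)**
score — the standard clinician-rated disability measure in multiple
sclerosis — from free-text clinic notes.

The EDSS is an ordinal scale from 0 (normal neurological examination) to
10 (death due to MS) in half steps, built from eight functional-system
subscores. Clinics dictate it inside consult notes; research databases
need it as a number. `edssnlp` provides the three models used to automate
that abstraction, and everything needed to evaluate and compare them:

* **Rule-based extraction** — sentence splitting, then the first sentence
  where the keyword "EDSS" co-occurs with an in-range half-step number
  yields the score (left-most number in that sentence); no mention means
  the extractor abstains. Functional-system subscores come from
  finding-pattern + severity-adjective rules (`subscore_rules.yaml`).
* **A convolutional text classifier** over skip-gram word embeddings
  trained on the note corpus itself: parallel convolutions (kernel widths
  3/4/5), max-over-time pooling, dropout, softmax over the 19 half-step
  classes plus an explicit *unknown* class. Both the embedding trainer and
  the CNN are compact, fully seeded implementations in vectorized R.
* **A cascade (combined model)** — the rule first; the classifier only
  when the rule abstains, so explicitly scored notes are always returned
  verbatim.
* **Evaluation protocol** — strict and converted accuracy (±1 tolerance
  for subscores), macro precision/recall/F1 with abstention-aware
  counting, unknown-prediction rates, exact/Monte-Carlo Pitman
  permutation tests, and leakage-free patient-level splits and k-fold CV.
* **A synthetic corpus generator** — seeded clinic notes with ground
  truth: explicit mentions in 62.3% of notes, heavy class imbalance
  (79.5% of scores in 0.0–4.0, 7.9% above 6.0), conflicting double
  mentions, spelled-out scores, qualitative-only notes, and per-system
  finding sentences. Real MS clinic notes are protected health
  information; every component of this package is testable without them.

All user-facing functions take a data frame of notes
(`note_id`, `patient_id`, `text`, optional labels) and return tibbles, so
pipelines compose with the pipe; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

The classic failure mode of rule-based extraction — a note that reports
the previous visit's score first — and a rule-model evaluation on a
synthetic corpus:

```r
library(edssnlp)
library(dplyr)

note <- tibble::tibble(
  note_id = "n1", patient_id = "p1",
  text = "EDSS was 5.0 in the previous visit. EDSS is 6.0 in this visit."
)
extract_edss(note)[, c("note_id", "edss_total", "source")]
#> # A tibble: 1 × 3
#>   note_id edss_total source
#>   <chr>        <dbl> <chr>
#> 1 n1               5 rule
```

The extractor returns 5.0 — the *first* mention, not the current score.
That error is intentional and tested: the rule model reproduces it
faithfully, and the cascade exists because of it.

```r
corpus <- simulate_notes(synth_config(n_patients = 150, seed = 1)) # 523 notes
preds  <- predict_edss(corpus, mode = "rule")
d      <- left_join(preds, corpus[, c("note_id", "edss")], by = "note_id")
glance(evaluate_edss(d, truth = "edss", estimate = "value"))
#> # A tibble: 1 × 8
#>   n_notes accuracy converted_accuracy unknown_prediction_rate macro_precision
#>     <int>    <dbl>              <dbl>                   <dbl>           <dbl>
#> 1     523    0.547              0.556                   0.394           0.838
#>   macro_recall macro_f1 tolerance
#>          <dbl>    <dbl>     <dbl>
#> 1        0.565    0.658         0
```

The profile is the signature of a frequently abstaining rule model: it
abstains on 39% of notes (every note without an explicit digit mention),
which costs accuracy and recall but not precision. Training the
classifier and cascading closes that gap — `train_word2vec()` +
`train_edss_cnn()` + `predict_edss(mode = "combined")`; see the methods
vignette (`vignettes/edss-extraction-methods.Rmd`) for the full
pipeline, every modelling assumption, and the design decisions.

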