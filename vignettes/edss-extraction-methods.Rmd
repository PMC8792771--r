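---
title: "Extracting EDSS scores from clinic notes: models, assumptions, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting EDSS scores from clinic notes: models, assumptions, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The Expanded Disability Status Scale (EDSS) is the standard clinician-rated
measure of disability in multiple sclerosis: an ordinal scale from 0 (normal
examination) to 10 (death due to MS) moving in half steps, derived from
eight functional-system subscores (pyramidal, cerebellar, brainstem,
sensory, bowel/bladder, visual, cerebral, ambulation). Clinics record the
score inside free-text consult notes far more reliably than in structured
fields, so research databases are typically populated by manual
abstraction. This package automates that step with three models and the
full evaluation protocol needed to compare them:

1. **A rule-based extractor.** A note is split into sentences; the first
   sentence in which the keyword "EDSS" co-occurs with a number in
   [0.0, 10.0] on the half-step grid yields the score (left-most in-range
   number within that sentence). No mention means the extractor abstains
   (`NA`). Subscores use finding-pattern/severity-adjective rules.
2. **A convolutional text classifier.** Notes are cleaned to lowercase
   letter-only tokens, encoded as fixed-length id sequences, embedded with
   corpus-trained skip-gram vectors, and classified into the 19 half-step
   EDSS classes plus an explicit *unknown* class by a standard
   sentence-classification CNN (parallel kernels of widths 3/4/5,
   max-over-time pooling, dropout 0.5, softmax; RMSprop with early
   stopping).
3. **A cascade.** The rule runs first; only when it abstains is the note
   passed to the classifier. On explicitly scored notes the cascade is
   therefore bit-identical to the rule, and retraining the classifier
   cannot change those outputs.

## Two parallel text views

Letter-only normalization would destroy exactly the evidence the rule
path needs ("5.0", sentence boundaries), so preprocessing maintains two
views of every note. The *rule view* is boilerplate-stripped text with
punctuation and digits retained, split into sentences on `.`/`!`/`?`
followed by whitespace — a period flanked by digits ("5.0") is never
followed by whitespace and therefore never splits. The *model view*
applies the full chain: boilerplate stripping, lowercase letter-only
tokenization, stop-word removal against a frozen English stop-word list
shipped in `inst/extdata` (no run-time downloads), vocabulary encoding
(minimum corpus frequency 2, id 0 reserved for padding and
out-of-vocabulary tokens), and zero-padding/truncation to `max_len`
(default 1000 tokens, the premodeling choice appropriate for consult
notes; the examples in this package use shorter lengths). Numeric tokens
are *not* restored for the model path; the classifier must rely on
qualitative language, which is what makes the cascade's division of
labour meaningful.

Boilerplate patterns (headers, fax/document numbers, dates, signatures)
are configuration, not code: real EHR exports differ by institution, so
the shipped defaults target the synthetic generator's templates and are
meant to be replaced in other deployments.

## Rule design choices

* Numeric mentions accept integer and decimal forms; values whose
  doubled value is not an integer (e.g. "6.25") are rejected because the
  EDSS grid is half-step. 0.5 and 10.0 are admitted at extraction time
  and flagged at class-mapping time (0.5 does not exist on the scale;
  10.0 does not occur in clinic notes).
* Spelled-out numbers ("EDSS was three") are deliberately not parsed:
  this is a characteristic failure mode of rule-based extraction that
  the package preserves and tests for, rather than papering over.
* Negation, temporality ("previous visit" vs "this visit") and
  coreference are out of scope for the rule model; the
  first-occurrence/left-most rule *will* pick an earlier score when a
  note reports two — again preserved as a positive test.
* The full severity-mapping tables used in specialist clinics derive
  from the proprietary Neurostatus scoring definitions; the shipped
  `subscore_rules.yaml` is a documented, editable stand-in covering all
  eight systems with monotone severity maps
  (minimal/mild/moderate/significant/severe/profound). Correctness of
  the extractor is defined against this file. A severity adjective must
  occur in the same sentence as the finding pattern, mirroring the
  same-sentence rule of the total score; when several adjectives occur
  in the sentence, the strongest wins.

## The embedding and the classifier

No deep-learning framework is assumed: both learners are compact,
fully seeded reference implementations in vectorized R.

**Skip-gram with negative sampling.** Architecture choice (skip-gram,
5 epochs, 5 negatives) reflects small-corpus behaviour; both the
architecture alternatives and the epoch count are configurable.
Candidate context pairs are enumerated once; a pair at distance *d* is
kept with probability *(window − d + 1)/window* per epoch (the standard
dynamic window); negatives come from the unigram distribution raised to
3/4. Updates are mini-batched, aggregating duplicate rows by their mean
— one averaged update per distinct token per batch — which keeps
frequent tokens stable at learning rate 0.05; the batch size scales with
corpus size so small corpora still receive many updates. Training is
single-threaded and deterministic given the seed. The embedding matrix
consumed by the classifier has the zero padding row at index 0 and zero
rows for vocabulary tokens without a trained vector. Note the distinction
between this lookup table (*V*+1 × dim) and the per-note input tensor
(`max_len` × dim) that the convolutions see.

**The CNN.** One branch per kernel width; each branch convolves the
embedded sequence, applies ReLU and max-over-time pooling; pooled
features are concatenated (3 × 100 = 300 features at the defaults),
passed through inverted dropout (rate 0.5, training only) and a dense
softmax layer. Loss is categorical cross-entropy; the optimizer is
RMSprop (ρ = 0.9). Weights are Glorot-uniform initialized. Early
stopping monitors validation loss with `patience` tolerated
non-improving epochs (0 = stop at the first) and restores the
best-validation weights. The embedding table is frozen by default;
fine-tuning is a flag, and the padding row is never updated in either
mode. Argmax decoding breaks exact ties toward the lower EDSS class
(classes are ordered ascending, unknown last), a conservative choice on
an ordinal disability scale.

**Abstention.** How a classifier should say "no score" is genuinely
open. The default makes *unknown* an explicit output class trained on
notes whose reference label is missing — abstention is learned, not
thresholded. The alternative (abstain when the maximum class probability
falls below `abstain_threshold`) is provided as configuration; in that
mode unlabeled notes are dropped from training. Both modes are tested;
the class-based mode is the default because it introduces no free
threshold parameter.

Learning rate, batch size, patience and filter count are tunable
configuration with defaults (1e-3, 32, 3, 100) chosen for the full-size
setting; like any CNN of this family the model is sensitive to the
learning rate at small problem sizes, and the worked examples in the
package select it by validation loss.

## Evaluation protocol

* **Strict accuracy** scores every note; the unknown label behaves like
  a class (an unknown prediction is correct only against an unknown
  reference). Exact match for the total score; subscores are scored
  within ±1 point.
* **Converted accuracy** drops unknown-reference notes first — the
  post-hoc regime for reporting performance on notes with valid scores.
  Both regimes are always reported, so either reading of a headline
  number is reproducible.
* **Macro precision/recall/F1** treat each scored class equally.
  Unknown is *not* a scored class: unknown-reference notes are excluded
  from the confusion table, and an unknown prediction against a known
  reference is a false negative for the reference class and a false
  positive nowhere — abstention costs recall and accuracy, never
  precision, which is exactly why a high-precision/low-recall profile is
  the signature of a frequently abstaining rule model. Classes absent
  from both predictions and references drop out of the macro mean;
  a scored class with a zero denominator contributes 0.
* **Pitman permutation tests** compare two models on the same notes by
  swapping their outcomes within pairs: exact enumeration of all 2^n
  patterns up to n = 20 (implemented by the doubling construction of
  the swap-sum distribution), Monte-Carlo beyond, with the observed
  pattern included so p ≥ 1/(B+1); two-sided counting uses
  |statistic| ≥ |observed| with a 1e-12 guard against floating-point
  ties. The macro-F1 statistic is not decomposable per note, so that
  variant swaps the two models' predicted labels and recomputes both
  macro F1 values per pattern (exact limit 14 for cost reasons).
* **Patient-level splitting.** Notes of one patient always share an
  assignment, in both the 80/20 split and the k-fold partition —
  leakage-free by construction, and tested across thousands of random
  corpora.

## The synthetic corpus

Real MS clinic notes cannot be shipped. The generator in
`simulate_notes()` replaces them with a seeded, fully documented
emulation of the statistical structure that matters to the pipeline:

* explicit "EDSS *x*" dictation in 62.3% of notes;
* heavy class imbalance — 79.5% of scores in 0.0–4.0, 7.9% above 6.0,
  the remainder in 4.5–6.0, uniform within bands;
* occasional double mentions where a previous-visit score precedes the
  current one (10% of explicit notes) — the documented first-occurrence
  trap, generated so the trap *must* spring;
* spelled-out scores ("EDSS was three"; 10% of non-explicit notes);
* withheld reference labels (5%) to train and test abstention;
* per-system finding sentences phrased as keyword + severity adjective,
  consistent with the shipped rule file, omitted with probability 0.3
  (and dictated as normal-exam lines when the subscore is 0, so the rule
  abstains there — realistic missingness for the subscore task);
* longitudinal plausibility: a patient's score performs a half-step
  random walk across visits (move probability 0.05 per direction),
  mild enough that realized band masses stay within sampling error of
  the configured distribution;
* a mean of 3.5 notes per patient (uniform 1–6), matching the
  note-to-patient ratio of a large clinic corpus.

Implicit notes must be learnable, or the classifier arm of the cascade
would be untestable. A note without an explicit score therefore carries
a qualitative anchor phrase paraphrasing the clinical content of its
half-step (ambulation distances spelled as words, aid requirements,
functional-system burden); every note carries a coarser severity-band
filler word (bands 0.0 / 1.0–2.5 / 3.0–4.0 / 4.5–5.5 / 6.0–6.5 / ≥7.0)
and per-system finding sentences. Restricting the fine-grained anchors
to implicit notes mirrors clinical dictation — the qualitative summary
substitutes for the score rather than duplicating it — and gives the
cascade its intended division of labour: the rule is the stronger model
exactly where the score is written, the classifier where it is not.
This is an idealization: the class signal in the templates is far
cleaner than in real dictation, so a high accuracy on synthetic
implicit notes demonstrates that the pipeline *can* learn
band-and-anchor vocabulary, not that it would reach the same accuracy
on real notes. Conversely the failure modes (distractor
mentions, spelled-out numbers, qualitative-only notes) are faithfully
reproduced and asserted as failures of the rule path. Template richness
(~40 templates, a vocabulary of a few hundred words) is an editable
free choice in `note_templates.yaml`.

## Problem sizes and numerical choices

The shipped tests exercise the full pipeline at reduced dimensions
chosen as honest surrogates: 2,000-note corpora, 50-dimensional
embeddings, 200-token sequences and at most 10 training epochs for the
end-to-end learnability check; a 1,000-note corpus for cascade fidelity;
10,000 random corpora for split hygiene; 1,000 random vectors against a
brute-force confusion-matrix oracle for the metrics. Scores are compared
on the half-step grid with a 1e-9 tolerance; probability vectors are
validated to sum to 1 within 1e-6; log-loss clamps probabilities at
1e-12. Degenerate inputs (empty corpora, empty class lists, all-unknown
references, fewer than two patients) raise errors rather than returning
silent zeros.

## Known limitations

* The rule extractor inherits every limitation it is designed to
  reproduce: no negation handling, no temporality, no spelled-out
  numbers, no "E.D.S.S."-style variants.
* The subscore rule table is a stand-in, not a clinically validated
  mapping.
* The classifier implementations favour clarity and reproducibility
  over speed; they are single-threaded and appropriate for corpora of
  tens of thousands of notes, not millions.
* The generator does not model real clinical language (no spelling
  noise, no OCR artifacts, no non-English text), and its class signal
  is idealized as described above.
* Cross-sectional only: the package extracts scores from single notes
  and makes no claims about predicting disability progression.
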