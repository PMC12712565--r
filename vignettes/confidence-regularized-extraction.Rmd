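---
title: "Confidence-regularized clinical feature extraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-regularized clinical feature extraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notegate)
```

## The problem

Rubric-based scoring of patient notes asks, for each case-specific clinical
feature (a symptom, a history element), whether a free-text note documents
it. When a generative extractor produces the candidate feature mentions, two
failure modes dominate: *hallucinations* — asserted features with no
supporting text in the note — and *misses* — documented features the
extractor never surfaces. notegate implements the computational machinery
around such an extractor: similarity primitives, a confidence-regularized
training objective that penalizes overconfident errors, an inference-time
matching gate that only accepts text-supported extractions, and the
evaluation/calibration harness that quantifies all of the above. The
extractor itself is abstracted behind a generator contract; a seeded mock
extractor stands in for it so every component is testable end to end with no
clinical data and no model training.

## Similarity primitives

All comparisons run on normalized text (lowercased, whitespace collapsed).
The workhorse is a character n-gram F1 (`chrf_f1()`): precision and recall
of the clipped-multiset n-gram intersection, combined harmonically. The
n-gram order defaults to `n = 3` (configurable 1–6). Three further choices:

* **Clipped multiset, not set, intersection.** Repeated grams ("aaa…") are
  counted up to their minimum multiplicity on either side, which is robust
  for repetitive clinical strings; `set_semantics = TRUE` switches to
  presence/absence counting.
* **Spaces count as characters**, so cross-word grams carry signal about
  word order and adjacency.
* **Short-string convention:** when either string is shorter than `n`,
  the score is 0 unless the normalized strings are equal, in which case it
  is 1 — exact matches of very short features ("LMP") are never zero-scored.

A single-order score is used rather than a multi-order chrF average, and
precision and recall are weighted equally (harmonic mean, no recall
weighting). Token overlap (`token_overlap_fraction()`) is *gold-relative*:
the fraction of the gold phrase's distinct tokens recovered by the
prediction, so it asks "how much of the credited phrase did we get"
rather than "how much of the prediction is right". TF-IDF cosine fits its
vocabulary on the supplied corpus (out-of-vocabulary tokens are dropped, as
in a standard TF-IDF fit) with smoothed IDF `log((1+N)/(1+df)) + 1`. The
embedding cosine is a *contract*: any string-to-vector function can be
plugged in; the package ships a deterministic bag-of-words embedder
(`bow_embedder()`), and a real sentence-embedding model is an optional
adapter, deliberately not a dependency.

## From token probabilities to feature confidence

Each extracted feature carries a sequence of token probabilities. The
pipeline (`feature_confidence()`) is:

1. **Aggregation** — the geometric mean `exp(mean(log p))`. We chose this
   as the single operation that is simultaneously an average and a length
   normalization: a constant-probability sequence scores the same at any
   length, so long features are not penalized merely for being long at this
   stage.
2. **Complexity adjustment** — `c^(1 + tokens/lambda)` with `lambda = 20`.
   Longer features are harder to extract exactly, so their confidence is
   shrunk; the power form is identity at zero tokens, fixes `c = 1`,
   preserves ordering, and stays in (0, 1]. The functional form is this
   package's design (the normalizer's published description fixes only
   `lambda`), exposed as a config knob.
3. **Stochastic noise** (training only) — additive Gaussian with standard
   deviation `beta * noise_base_sd` (defaults 0.2 × 0.05), clipped to
   `[1e-4, 1 - 1e-4]`. The noise keeps confidences from collapsing to
   degenerate values during training; it is seeded, and disabled at
   inference or when `beta = 0`, which makes the whole pipeline
   deterministic.

Two pieces of epoch-level machinery stabilize training. The overconfidence
threshold follows a curriculum: `dynamic_threshold()` rises linearly from
`tau_init = 0.6` at epoch 0 to `tau_final = 0.7` at the last epoch. An
F1-coupled variant (`f1_coupled_threshold = TRUE`) interpolates by the
previous epoch's F1 instead; we provide both because the two published
descriptions of the schedule emphasize different drivers (epoch progression
vs the prior epoch's F1), and default to the linear schedule, which is
monotone by construction. Cross-epoch confidence estimates are smoothed by
an EMA (`ema_feedback()`, weight 0.7 on history).

## Bidirectional matching and the penalty algebra

For each note, every non-empty prediction is matched *forward* against all
gold features (max chrF F1), and every gold feature *backward* against all
predictions. Per-feature argmax is intentional — no bipartite assignment —
so one prediction may cover several gold features and vice versa.

* **Hallucination side:** a prediction's penalty base is `1 - F1` when its
  best forward match is ≤ 0.3 and the reduced `0.7 * (1 - F1)` when it is
  > 0.3 (strict), so partially supported extractions are penalized more
  gently. The base is then gated and scaled by the confidence:
  `overconfidence_penalty()` is 0 whenever `c <= tau` or the base is 0, and
  `base * (c + 2 * (c - tau)^2)` otherwise — proportional to the confidence
  with a quadratic term above the threshold (scaling factor
  `alpha_penalty = 2`). This composition — base times (confidence plus
  quadratic excess) — is our design; the published constraints (confidence
  proportionality, quadratic overconfidence term, `(1 - F1)` as the error
  measure, zero penalty at or below threshold) do not pin down the
  composition, and an alternative `base * alpha * (c - tau)^2` form is kept
  behind `penalty_form = "quadratic_only"`.
* **Missing side:** gold features whose best backward match is < 0.5
  (strict) contribute `1 - F1`. The aggregation over a note's gold features
  is the mean over *all* gold features (`mean_all`), so the penalty scales
  with the fraction of the rubric missed; `mean_missing` and `sum` are
  available. The published aggregation formula is not recoverable from the
  available text (an unreadable figure), so this is a declared stand-in.

The note-level loss is the exact linear form
`total = ce + 0.2 * hallucination + 0.5 * missing`; the missing penalty is
weighted higher to push recall. When both penalties are zero, the loss
breakdown carries `penalty_gradient = FALSE` — a differentiable
implementation must skip the penalty backward pass entirely in that case.
`run_epoch()` drives an abstract generator over a corpus for one epoch,
aggregates penalties per note and per case, computes the epoch's
binary-overlap F1 on the training slice (the cheapest metric consistent
with evaluation; the matching gate is not run inside the training loop) and
feeds F1 and EMA-smoothed confidence into the next epoch's state.

## The matching gate

At inference, every asserted extraction must be located in its note before
it can count:

1. **Exact / Levenshtein** — a whitespace-flexible, case-insensitive
   literal search (leftmost hit); failing that, the best token-aligned
   window whose punctuation-stripped text reaches normalized Levenshtein
   similarity ≥ 0.85 (roughly one edit per seven characters — single-typo
   misspellings pass, rewordings do not).
2. **Sentence TF-IDF** — the best note sentence by TF-IDF cosine (the
   note's own sentences are the background corpus; rule-based splitting on
   `. ; ! ?` and newlines — clinical notes are choppy and a sentence model
   would be a heavy dependency for little gain). If it reaches 0.5, the
   extraction's tokens are aligned to the sentence's matching token runs,
   yielding possibly discontinuous evidence spans.
3. **Windowed overlap** — a sliding token window of the extraction's
   length + 2 slack tokens; the best window with ≥ 50% of the extraction's
   tokens wins, the span covering its matched tokens.

First success wins and records its method; ties break leftmost, then
shortest. All four thresholds are this package's defaults — the three-step
design fixes the methods, not the numbers — and sit in `gate_config()`.
Every validated decision's spans index the *original* note text and
reconstruct the matched text exactly; this soundness property is asserted
on every synthetic corpus run in the test suite. The gate is applied
identically to any extractor variant being compared.

## Evaluation, calibration, error accounting

Two presence modes, never mixed: **binary overlap** (present iff
gate-validated and ≥ 50% of gold tokens recovered; a validated extraction
for a gold-absent feature is a false positive) and **semantic** (present
iff gate-validated and embedding cosine against the rubric description
≥ 0.5, with 0.5–0.7 flagged borderline for review). Precision, recall and
F1 use the conventions: no predictions with gold present → all 0; neither →
all 1.

Calibration deliberately uses *continuous* feature-level chrF scores
against gold, not binary outcomes, paired with pipeline confidences: ECE is
the count-weighted mean absolute gap between per-bin mean confidence and
mean score over the four bins 0.6–0.7, 0.7–0.8, 0.8–0.9, 0.9–1.0, plus (by
default, excludable) an underflow bin [0, 0.6) so low-confidence
predictions are not silently dropped. The reliability table reports both
the signed confidence gap (`mean_score - mean_confidence`) and
`gap_to_optimum = mean_score - 1`, the bin's distance below perfect
performance. The Brier score is `mean((c - s)^2)` on the same pairs.

The error ledger counts a feature as hallucinated when it is *asserted* on
a gold-absent feature — by default including gate-rejected assertions (an
extractor that asserts what the gate cannot find has hallucinated;
`count_rejected = FALSE` counts only validated false positives) — and as
missing when a gold feature is not predicted present. Rates and percent
reductions are rounded half-up to one decimal for reporting; raw counts are
retained. Paired model comparisons bootstrap the F1 difference by
resampling *notes* (the test-set unit) with a percentile 95% CI, and run a
McNemar test on per-feature correctness: exact binomial below 25 discordant
pairs, chi-squared with continuity correction otherwise.

## What the synthetic generator does and does not emulate

`generate_corpus()` builds templated notes from a 40-concept symptom bank:
10 cases × 10 notes × 14 rubric features by default, each feature
documented with probability 0.7, mentions paraphrased (0.3), typo'd by a
single edit (0.1), or expressed as a pertinent negative (0.15) — rubrics
credit documented negatives, so a negated mention still carries a gold
span. Gold spans are recorded as exact offsets of the inserted surface
form, so every annotation satisfies the span-reconstruction invariant by
construction. The mock extractor misses documented features at rate 0.2 and
fabricates mentions (verifiably absent from the note) at rate 0.1, both
decaying by 0.5 per epoch to emulate training improvement; confidences are
Beta(10.5, 2) (mean 0.84) for truthful and Beta(5, 2) (mean 0.71) for
fabricated extractions, mirroring the stable ≈0.84 mean confidence regime
with enough separation for the overconfidence penalty to discriminate.
These defaults are the package's fixed study conditions, not tuning dials.

What passing tests on this corpus show: the algebra, gating, accounting and
calibration machinery behave exactly as documented here under controlled
error structure. What they do not show: performance on real clinical language —
the generator has no abbreviation soup, no copy-forward noise, no negation
scope ambiguity, no out-of-template paraphrases, and its vocabulary is
closed (which also makes the bag-of-words embedder unrealistically strong
in semantic mode). Conclusions about real notes require real notes.

## Numerical choices and degenerate inputs

The 0.3 (reduced-penalty) and 0.5 (miss) cuts are strict inequalities;
ties at a threshold take the conservative branch. Empty
predictions and empty gold sets yield zero penalties of the corresponding
type. Two empty strings are Levenshtein-identical (similarity 1); an
all-punctuation token normalizes to nothing and can never validate a gate
match. Probabilities of exactly 0 are rejected at the contract boundary
(they would make the geometric mean degenerate). The bootstrap and all
noise injection are seeded; everything else is deterministic, and the test
suite asserts bit-identical reruns where determinism is claimed.

Problem sizes in the shipped tests and the acceptance script (oracle
batteries of 1000 pairs, corpora up to ~2100 feature slots, 5-epoch series,
2000 bootstrap replicates) were chosen as the smallest sizes at which the
statistical assertions have comfortable margins — e.g. rate recovery is
tested at n ≥ 2000 against a 3-standard-error band.

## Known limitations

* The complexity adjustment, noise distribution, missing-penalty
  aggregation and overconfidence-penalty composition are declared design
  choices where the published description fixes only parameter values;
  all four are configurable, and sensitivity to them is not explored here.
* The gate's thresholds are defaults, not fitted values; on real notes they
  would deserve a calibration pass.
* `run_epoch()` treats the generator as a black box and the cross-entropy
  term as an input; wiring a real differentiable model (and honoring the
  no-penalty/no-gradient contract in its backward pass) is adapter work
  outside this package's tested surface.
* Semantic evaluation with the bundled bag-of-words embedder degrades on
  paraphrases that share no tokens with the rubric description; that is a
  property of the test embedder, not of the semantic-evaluation logic.
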