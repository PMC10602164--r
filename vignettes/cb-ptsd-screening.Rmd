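---
title: "Screening childbirth narratives for probable CB-PTSD: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening childbirth narratives for probable CB-PTSD: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbscreen)
```

## The screening problem

Childbirth-related post-traumatic stress disorder (CB-PTSD) affects a
significant minority of postpartum women and has no standard screening
protocol. The signal this package exploits is the free-text birth story: a
short, unstructured account of a recent delivery, collected alongside the
PTSD Checklist for DSM-5 (PCL-5). The pipeline's job is to predict, from
the narrative text alone, whether the author's PCL-5 total falls at or
above the clinical cutoff.

## Labeling: PCL-5 scoring

The PCL-5 has 20 items, each scored 0–4, so totals range 0–80. Two scoring
conventions are built in and fixed:

* **missing items are coded 0** (`score_pcl5()`), which can only lower a
  total — the derived label therefore errs toward the negative class for
  incomplete questionnaires, and a record with *all* items missing is
  scored 0 but flagged in a message;
* **the positive class is total ≥ cutoff**, with cutoff **31** by default
  (`assign_class()`), the high-specificity choice for provisional PTSD
  screening in postpartum samples. The cutoff is exposed as a parameter
  because the literature supports 31–33.

`cronbach_alpha()` is provided as a reliability utility for item matrices
(the instrument is highly internally consistent in real samples, α ≈ 0.93);
it plays no role in classification.

## Corpus preparation

Narratives with fewer than **30 words** are discarded
(`filter_by_word_count()`); shorter texts carry too little signal to embed
meaningfully. The tokenizer is deliberately minimal — split on runs of
whitespace after trimming — because any richer rule would be an arbitrary
choice the results should not depend on; the same counter is used
everywhere a word count is needed.

Class imbalance (positives are the minority) is handled by
**down-sampling** the majority class uniformly at random to the minority
size (`balance_downsample()`). Per repeat, each class then contributes
`train_per_class` (default **170**) training narratives, the remainder
forming the test set (`split_train_test()`); with 190 records per class
after balancing this leaves 20 test narratives per class. Repeats re-draw
both the down-sampling and the split with seed `base_seed + repeat_index`
— independent random splits, not disjoint folds, since per-class test sets
of 20 cannot tile 190 records into 10 disjoint folds.

## Embeddings

Everything downstream consumes fixed-length numeric vectors through a small
backend contract (`embedding_backend()`): a name, a dimension (default
**1536**, matching the hosted embedding provider the pipeline was designed
around), and a text-to-vector function. Backends with other dimensions plug
in unchanged because all downstream stages read the dimension from the
backend or the cache, never hard-code it. Three backends ship:

* an **external-adapter slot**: any function wrapping a remote provider can
  be passed to `embedding_backend()`; no network code lives in the package
  and no test touches a network;
* a **deterministic offline backend** (`offline_backend()`): hash of the
  text's UTF-8 bytes seeds a pseudo-random unit vector — stable across
  processes, useful for exercising plumbing, carrying no semantics;
* the **synthetic backend** (`generate_embeddings()`, below), which carries
  controllable class signal.

Offline and synthetic vectors are unit-norm: the production provider emits
near-unit-norm vectors, and the Hadamard feature is scale-sensitive, so the
emulators should live on the same sphere. `cache_embeddings()` memoizes
vectors by record id (re-embedding nothing on reruns) and refuses an id
reused with different text. Over-length inputs are a backend concern: an
adapter should fail loudly rather than silently truncate.

## Pairwise augmentation

With only a few hundred labeled narratives, the pipeline trains on *pairs*:

* **Set 1**: all C(k, 2) unordered pairs within the positive class;
* **Set 2**: all C(k, 2) unordered pairs within the negative class;
* **Set 3**: `neg_ratio` × C(k, 2) cross-class pairs (default ratio 2, so
  negatives exactly balance positives), sampled uniformly from the k × k
  cross grid — **without replacement** whenever the requested count fits in
  the grid (true at the defaults: 28,730 ≤ 170² = 28,900), avoiding
  duplicate training rows; with replacement otherwise.

At k = 170 this yields 14,365 + 14,365 + 28,730 = **57,460** examples. The
pair feature is the Hadamard product `z = emb(u) ∘ emb(v)` — symmetric in
its arguments, so pairs are stored canonically (`id_a < id_b`) and the
feature is invariant to member order by construction. Within-class pairs
are labeled 1 ("similar"), cross-class pairs 0.

## The similarity network

`train_model()` fits a feedforward network: input = embedding dimension,
hidden layers of **400 and 50** ReLU units (configurable), one sigmoid
output; Adam with learning rate **1e-4**, batch size **32**, binary
cross-entropy, at most **50** epochs. A **20%** validation holdout,
stratified by pair label to preserve the 50/50 balance, is carved out
reproducibly from the model seed; training stops when validation loss fails
to improve for **3** consecutive epochs, and the best-epoch weights are
restored. Numerical choices worth stating:

* *monitored loss*: validation loss — a validation set is explicitly carved
  out, so it, rather than training loss, drives early stopping; both are
  recorded per epoch in `model$history` so either policy is auditable;
* *improvement tolerance*: a decrease must exceed 1e-6 to count, so float
  noise cannot postpone stopping indefinitely (with learning rate 0,
  training provably stops at epoch patience + 1);
* *initialization*: fan-in-scaled (He) normal weights, zero biases, seeded
  from the config; predictions are bitwise reproducible for a fixed seed;
* *loss clipping*: predicted probabilities are clipped to [1e-7, 1 − 1e-7]
  inside the loss only.

The network and its Adam optimizer are implemented directly in base R
matrix algebra; at these layer sizes the mini-batch updates are small dense
products that BLAS handles comfortably. Models serialize to a versioned
directory (`save_model()`/`load_model()`) with exact prediction round-trip.

## Inference: anchor-mean classification

The trained model scores pairs, not single narratives. To classify an
unseen narrative, `classify_narrative()` pairs its embedding with every
training narrative of each class (the class **anchors**), predicts each
pair's similarity, and averages per class; the larger mean wins. This is
the minimal single-narrative protocol consistent with a pair-similarity
model that must emit hard labels. Two tie/design choices are exposed as
documented defaults rather than hidden:

* all training narratives of a class serve as anchors (no subsampling rule
  is imposed);
* an exact tie predicts class 0, favoring specificity — for a screening
  instrument a tie should not raise an alarm.

Predictions are invariant to anchor ordering (the mean is order-free), and
a constant-output model always predicts class 0 by the tie rule.

## Evaluation

Because the pipeline emits hard 0/1 labels, its ROC has a single operating
point: the "stepped" polyline (0,0) → (1 − specificity, sensitivity) →
(1,1), whose trapezoidal area reduces to **AUC = (sensitivity +
specificity)/2** (`binary_auc()`; the closed form is verified against
generic trapezoidal integration in the tests). `confusion_metrics()`
computes sensitivity, specificity, precision and F1 = 2TP/(2TP + FP + FN);
when nothing is predicted positive, precision is undefined and F1 is 0 with
a warning (the standard screening convention). `run_repeats()` executes the
full cycle `n_repeats` times (default 10) and reports per-repeat rows plus
their unweighted mean — test sets are equal-sized by construction, so no
weighting is needed. Metrics are kept at full precision; two decimals is
the conventional reporting scale.

## Prompt-model baselines

`prompt_template()` ships the published zero- and few-shot prompt templates
as text assets; `render_prompt()` substitutes the narrative (and, few-shot,
the labeled examples, one per class by default, up to four supported)
verbatim into the quoted slots. The chat-backend contract fixes temperature
at 0, making responses a pure function of the prompt; `mock_chat_backend()`
wraps any responder function so the whole path is testable offline.
`parse_response()` is deliberately strict: after trimming whitespace and
surrounding quotes, only a bare `"0"` or `"1"` parses — the prompt forbids
anything else, and salvaging digits from verbose answers would silently
corrupt evaluation. Unparseable or failing records go to a failure log and
are excluded from metrics, never defaulted to a class. Parsed labels feed
the same evaluator as the embedding pipeline.

## The synthetic-data generator

Real survey data for this task are not publicly deposited, so
`generate_survey()` builds complete synthetic studies with the statistical
structure the pipeline assumes. What it emulates, and what it does not:

* **Embeddings** (`generate_embeddings()`): two centroids at distance
  `separation` along a random direction, isotropic Gaussian noise
  (`noise_sd`), renormalized to the unit sphere. `separation` is the single
  dial between a null world (0: AUC ≈ 0.5 end to end) and a separable one
  (≈ 2.5 with noise 0.25: F1 ≈ 1). Embeddings are generated directly from
  class labels, *not* derived from the synthetic text — the production
  text-to-vector map is an external black box, and emulating it would test
  nothing; the text generator exists to exercise filtering, I/O and prompt
  plumbing, meeting the embeddings only at the record id.
* **PCL-5 items** (`generate_pcl5()`): each record draws an item propensity
  on the logit scale around its class parameter (class 1: p = 0.60, class
  0: p = 0.12, jitter sd = 0.4 — chosen once so class-1 totals reach the
  cutoff with probability ≥ 0.95 and class-0 totals average ≈ 10, and so
  the record-level jitter induces the within-respondent item correlation of
  a severity scale), then 20 Binomial(4, p) items; items go missing
  independently at `missing_rate` (default 0.005, roughly the 1%-of-records
  order seen in real administrations). Ground truth is *defined* as the
  scored total against the cutoff, so labels always agree with the scoring
  rule; `force_class = TRUE` redraws the rare record whose realized class
  misses its intended one, giving exact class counts when a fixture needs
  them.
* **Narratives** (`generate_narratives()`): filler words from a small
  vocabulary at negative-binomial word counts with the class means observed
  in real data (194.67 / 155.39 words) and dispersions (1.7 / 1.0) matched
  to the reported median/mean skew; a configurable `fraction_below_min` is
  drawn under 30 words to exercise the filter, and optional class marker
  tokens support scripted prompt-backend mocks. No attempt is made to mimic
  the linguistic content of trauma narratives.

Passing tests on this generator therefore demonstrate that the *pipeline*
is correct — counts, labels, determinism, learnability when signal exists,
chance behavior when it does not. They say nothing about how well any real
embedding model separates real birth narratives, which is exactly the
question requiring clinical data.

A note on the null check: with an anchor-based hard-label classifier,
permuting labels while leaving a strongly clustered embedding space intact
produces *heavy-tailed* null metrics — the model overfits spurious rules
aligned with the surviving cluster axes, predictions correlate across test
narratives, and single-run AUC can land far from 0.5 in either direction.
The chance-behavior property is therefore asserted where it is well-posed:
labels shuffled over *uninformative* embeddings (separation 0), where AUC
concentrates tightly around 0.5. The clustered-null instability is a real
property of the method worth knowing before interpreting single-run results
on small test sets.

## Problem sizes used in the test suite

The suite exercises the full pipeline at desk scale, a deliberate design
choice so that properties can be checked across many seeds: embedding
dimension 8–48, hidden layers 64/16, 16–190 records per class, training
splits of 6–50 per class, with the protocol hyperparameters (Adam 1e-4,
batch 32, ≤ 50 epochs, patience 3, 20% validation) at their defaults
throughout. The exact combinatorics (14,365 / 28,730 / 57,460 pairs at
k = 170) are asserted at full k, where pair construction takes well under a
second; only network training is scaled down. The separability and null
properties each run over 5 seeds.

## Known limitations

* The single-narrative inference protocol (anchor means, tie to class 0)
  is a documented reconstruction of the minimal rule consistent with a
  pair-similarity model emitting hard labels; other reductions
  (e.g. subsampled anchors, calibrated thresholds) are possible.
* Repeats are independent random splits, not disjoint cross-validation
  folds; aggregate means are reported without dispersion, and no
  probability calibration or abstention band is provided.
* Down-sampling discards most majority-class data each repeat; the repeat
  loop recovers coverage in expectation but not by construction.
* The hard-label AUC identity means AUC adds no information beyond
  sensitivity and specificity; it is reported for comparability, not as an
  independent metric.
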