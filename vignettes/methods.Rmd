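---
title: "Methods: user-level suicidal-ideation screening from posting behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: user-level suicidal-ideation screening from posting behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinicians screening for suicidal ideation can only see the people who reach
them. Public social-media timelines carry signals — what people write, when
they post, how connected they are — that can be turned into a user-level risk
screen. `spvscreen` implements such a screen end to end: it distills a user's
timeline to the posts most related to suicidal ideation, extracts an
interpretable feature bank from that distilled profile, and evaluates
classifiers that separate at-risk users from two kinds of controls:

* **focused controls** — users who *use* suicide-related vocabulary without
  being at risk (news accounts, opinions, trivialization); the hard negative
  class, and
* **generic controls** — randomly sampled users; the easy negative class.

Because timeline data of real at-risk users cannot be redistributed, the
package ships a synthetic cohort generator with the documented group
contrasts planted, so every stage is testable and the whole analysis is
reproducible from a seed.

## Pipeline stages

### 1. Short profile version (SPV)

A tweet-level binary classifier (the *SPV classifier*, SPVC) is trained on a
labeled corpus of suicide-related vs. control posts: tf.idf-weighted word
n-grams of orders 1–5, a principal-component reduction retaining 95% of
variance (capped at one less than the corpus size), and a ridge-regularized
logistic scorer. Each user's SPV is then the at most **15** posts whose score
is **strictly above 0.5**, ordered by score with ties broken by recency and
then post id. Users whose posts all score at or below the threshold are kept
with `has_spv = FALSE`; their SPV-sourced features are later imputed, never
silently dropped.

Two numerical choices deserve a note. The reduction rank is chosen by a 95%
explained-variance rule because tf.idf spaces at this scale are nearly
isotropic and a fixed rank would be arbitrary. The logistic stage is
ridge-penalized (`lambda = 0.01` on the component scores): at ranks close to
the sample size an unpenalized fit is separable and its coefficients diverge.
The fitted scorer is algebraically collapsed to one weight per vocabulary
n-gram, so scoring half a million posts needs a sparse matrix–vector product
and never materializes component scores.

### 2. The SNPSY feature bank

Per user, 19 + K + 1 features (K = lexicon categories):

* **Behavioral (9)** — weekday and weekend posting ratios and the median gap
  in seconds between consecutive SPV posts; four quarterly posting ratios
  (fixed calendar quarters of the collection window's final year, normalized
  by the full-profile in-window count); and the sleep-time tweet ratio
  **STTR** with its complement **DTTR**. STTR divides the day into eight
  3-hour UTC slots, sums post counts over each of the eight *circular*
  adjacent slot pairs, takes the minimum — the inferred 6-hour sleep window —
  and normalizes by the user's total in-window post count. STTR is computed
  from the full profile (the feature registry's source), not from the SPV;
  the normalizer is the in-window post count, not the lifetime status count.
* **Tweet statistics (5)** — SPV-retention ratio, median SPVC score, median
  SPV tweet length in word tokens, SPV size, lifetime status count.
* **Relational (5)** — followers, friends, favorites given (metadata
  pass-throughs) and the medians of favorites and retweets received over SPV
  posts.
* **Lexicon (K)** — per category, greedy left-to-right, longest-match-first,
  non-overlapping phrase counts over the concatenated SPV tokens, normalized
  by the token total. The shipped lexicon is a small synthetic
  Spanish-flavored stand-in (proprietary category dictionaries cannot be
  redistributed); any JSON file of 1–3-token phrases can be plugged in.
* **Sentiment (1)** — the median per-post polarity over the SPV. The default
  scorer is a transparent word-list ratio mapped to [0, 1]; any per-post
  scorer can be substituted.
* **Image score** — the mean of per-image scores in [0, 1], produced by any
  external per-image model; the generator draws them from calibrated Beta
  distributions. Kept separate from the bank and appended only by the
  recipes that use it.

Users without an SPV (or with fewer than two SPV posts, for the gap feature)
get `NA`s that are filled with per-feature *training-set medians*; missing
image scores are filled with the training-set *mean*. Weekdays use the UTC
date, Monday first. Tokens are lowercase, punctuation-stripped whitespace
tokens.

### 3. User-level text models

Each user is a document: the concatenation of their post tokens, in the
full-profile variant or the SPV variant. After stopword removal, word n-grams
of orders 1–5 are weighted by smoothed tf.idf with L2 normalization (no
sublinear tf), and n-grams present in fewer than `ceiling(0.05 * n)` of the
documents are dropped — the floor applies to raw document frequency, before
weighting. The *BoW outputted feature* reduces such a matrix to a single
probability column without leakage: every training user is scored by a
ridge-logistic model fit on stratified folds excluding that user, and
held-out users by a model fit on the whole training set. Users with empty
documents receive the training class prior. The same construction yields the
*SNPSY outputted feature*.

### 4. Feature-combination recipes and evaluation

Ten recipes combine the three families — the two BoW baselines
(full-profile, SPV), the SNPSY bank alone, SNPSY plus the stacked BoW
column, BoW or SNPSY plus the image score, a 3-column ensemble (image score
+ both stacked columns; rows with a missing image score are dropped there,
elsewhere the score is mean-imputed), the full compact combination, and two
*selected-features* recipes keeping the pooled columns that pass a
two-sided Mann-Whitney U screen at α = .05 and α = .001 respectively. The
exact null distribution is used when the pooled sample size is at most 20
and untied; otherwise the tie-corrected normal approximation. Screening and
all transform parameters are computed from training rows only — the
permissive whole-sample variant is available behind
`screen_scope = "all"` for comparison, but the leakage-safe protocol is the
default.

Evaluation follows a fixed nested protocol: a stratified 70/30 split;
per-column Yeo-Johnson power transform with standardization fitted on
training rows; four candidate families (random forest, single-hidden-layer
perceptron, ridge-logistic, RBF support-vector machine) compared by mean AUC
under stratified 10-fold cross-validation; a 5-fold grid search on the
winner (small default grids: tree count 300 with two `mtry` values, two
layer sizes × two decays, four ridge penalties, two costs × two kernel
widths); a final fit on the full training set; and held-out precision,
recall, F1, accuracy and AUC for the risk class at a fixed 0.5 threshold —
threshold specialization is deliberately out of scope. Stochastic learners
are averaged over three seeded fits. Recipes are compared against the
full-profile text baseline with the DeLong test for paired ROC curves, and
feature relevance is reported both as mean impurity decrease of a random
forest and as absolute point-biserial class correlation.

The *overlapping index* used in the screening report estimates the integral
of the pointwise minimum of the two class densities: Gaussian kernels with
Silverman's bandwidth on a shared 512-point grid spanning the pooled range
plus three bandwidths, integrated by the trapezoidal rule; zero-variance
samples fall back to a shared-bin histogram.

## The synthetic cohort generator

`cohort_config()` defaults encode the study conditions the pipeline is
designed around: 84 users per group over a one-year window
(2017-12-21 – 2018-12-21); per-user post counts log-normal with medians
2797.5 / 2984 / 716 (risk / focused / generic); tweet lengths
shifted-Poisson with medians 11 / 19 / 14 tokens; friends counts log-normal
with medians 372 / 578.5 / 500; image scores Beta with medians 0.24 / 0.23 /
0.23 (concentration 10, solved for the exact Beta median); image counts from
the per-group image volumes, capped at 1000 per user, with 2% of users
missing images entirely. Posting hours follow an 8-slot circadian profile
with a sleep trough at 03:00–09:00 UTC; a group-specific *night propensity*
(0.03 / 0.015 / 0.01) adds mass to the trough, which puts the median STTR
near 0.04 for risk users and 0.02 for generic controls. Tweet text is drawn
from a unit mixture of filler pseudo-words, sentiment words and multi-token
lexicon phrases with per-group emission rates, so lexicon counting, n-gram
models and the sentiment scorer all see real signal. About 5% of focused
controls are generated as news-like informative accounts (no
suicide-related or self-referential vocabulary, a dedicated newsroom
vocabulary, heavy work/money topics); these are the users that end up
without an SPV. Where a generative parameter had no documented anchor
(spread parameters, followers/favorites medians, engagement rates), a value
plausible for a Twitter cohort was chosen once and kept.

The tweet-corpus generator for the SPVC exposes a `separation` dial: 0
makes the two classes lexically identical (a null corpus — the SPVC's
cross-validated F1 sits at chance), 1 uses the risk group's emission rates
(F1 ≈ 0.8 under the default contrasts), and values above 1 extrapolate the
contrast for a strongly separable corpus (F1 ≥ 0.9). Timestamps are
homogeneous in time apart from the circadian and weekend modulation; no
finer-grained burstiness is claimed.

What passing tests on this generator do **not** show: real timelines have
topic drift, code-switching, irony, platform artifacts and annotation noise
that no token-mixture model reproduces. The generator validates the
*machinery* — filtering, feature arithmetic, leakage-safe stacking,
screening calibration, evaluation protocol — not the clinical effect sizes,
which are only directional anchors here.

## Problem sizes used by the tests and the acceptance script

Most tests run a reduced cohort (20 users per group, post-count medians
250 / 270 / 70) chosen so the full suite stays fast while every planted
contrast remains detectable; the parameter-recovery checks run one cohort at
the full default volume (84 per group, ~600k posts). The replicate-based
directional checks (SPV-variant vs. full-profile text model; generic vs.
focused AUC ordering) use 15–25 seeded replicates at reduced volume. The
acceptance script evaluates the SNPSY models on the full-size cohort and the
calibration quantities (null screening rate, overlap index) at the sizes
stated in its output.

## Known limitations

* The SPVC's probability calibration near the 0.5 threshold is inherited
  from the ridge fit; no recalibration is attempted, matching the fixed
  decision threshold of the protocol.
* `wilcox.test`'s normal approximation is used for all but the smallest
  screens; exact mid-P variants are not implemented.
* The image pathway is a pluggable scorer plus calibrated synthetic scores;
  no image model ships with the package.
* Timestamps are UTC-only; per-user timezones are unknown by design, so
  day-level features absorb timezone error and the circadian features rely
  on the population-level trough.
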