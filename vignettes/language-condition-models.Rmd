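---
title: "Predicting medical conditions from patient language: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting medical conditions from patient language: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langdx)
```

## The problem

Given a cohort of participants who each contribute a corpus of short
social-media posts, a demographics table (age, sex, race), and binary
medical-condition labels (e.g. diagnosis categories derived from ICD codes),
`langdx` answers two questions:

1. *Prediction*: how well do language features predict each condition,
   compared with and in combination with demographics?
2. *Marker identification*: which individual language topics carry
   condition-specific signal beyond demographics, and how large is the
   associated risk contrast?

Because cohorts of this kind are typically private, the package ships a
synthetic cohort generator with known ground truth; every stage of the
pipeline is validated by parameter recovery on generated data.

## The patient language encoding

Each participant's posts are tokenized (lowercasing; URL and user-handle
placeholders; emoticons preserved; no stop-word removal or spelling
correction, since slang and misspellings are themselves informative) and
encoded as:

* **n-gram relative frequencies.** All unigrams and bigrams (bigrams never
  span post boundaries) are counted; the 20,000 most frequent grams
  corpus-wide (both orders pooled, ties lexicographic) form the candidate
  vocabulary. Frequencies are normalized within gram order, so a
  participant's unigram frequencies sum to 1 and their bigram frequencies
  sum to 1 before truncation.
* **Topic usage scores.** A 200-topic Latent Dirichlet Allocation model is
  fitted to the unigrams. From the fitted topic-word distributions
  $p(w \mid t)$ and the corpus-wide topic prior $p(t)$, Bayes' rule gives
  $p(t \mid w)$, and each participant's topic score is
  $$s_{u,t} = \sum_w p(t \mid w)\, p(w \mid u),$$
  where $p(w \mid u)$ is the participant's relative frequency of word $w$.
  With full vocabulary coverage each score row sums to 1. This weighting by
  the participant's probability of mentioning each word makes the score a
  usage probability rather than a document-fit quantity, and it can be
  computed for new participants without re-fitting the topic model.

Within each cross-validation training fold, the candidate grams are reduced
to the top 500 by family-wise-error-adjusted univariate association with the
condition (two-sided point-biserial correlation test, Bonferroni adjustment
across grams; ties broken by raw p-value, then lexicographically). The
statistic is deliberately simple and is exposed as a pluggable function;
any monotone transform of the per-gram p-value yields the same selection.
The 500 selected grams plus the 200 topic scores form the 700-dimensional
patient language encoding.

### LDA engine

No suitable topic-model implementation is available to this package, so the
model is fitted by a compact collapsed Gibbs sampler (written in C++). The
contract is on the outputs — stochastic $p(w\mid t)$ rows, a topic prior
equal to the expected corpus-wide topic proportions, $p(t \mid w)$ rows
summing to 1, and bit-reproducibility under a fixed seed — not on the
fitting algorithm. Defaults: document concentration $\alpha = 50/K$, word
concentration $\eta = 0.01$, 300 full sweeps. On the corpus scales this
package targets (hundreds to a few thousand participants, vocabularies in
the hundreds to low thousands), 100–300 sweeps reach stable topic recovery:
the test suite verifies that five well-separated planted topics are
recovered to mean total-variation distance below 0.2 after 100 sweeps, and
recovery of 20 planted topics in a 1,000-participant corpus is typically at
TV ≈ 0.1 by 100 sweeps. For much larger vocabularies the sweep count should
be raised.

## The three predictive models

For each condition, three models are compared under stratified 10-fold
cross-validation (all fitting, including gram selection, happens inside the
training folds; every participant receives exactly one held-out prediction
per model):

1. **Language**: extremely randomized trees (ERT) over the 700-dimensional
   encoding — 1,000 estimators, Gini impurity split criterion, one uniform
   random threshold per candidate feature, $\sqrt{d}$ candidate features
   per split, no bootstrap resampling. The forest is implemented in C++ in
   this package; the test suite cross-checks its held-out discrimination
   against an independent extremely-randomized-trees implementation
   (`ranger`) on planted-signal data. Trees are grown to purity by default
   (`min_node_size = 1`); the node size is configurable, which matters for
   probability calibration on weak signals (see *Numerical choices*).
2. **Demographics**: an L2-penalized (ridge) logistic regression over
   standardized age, sex, and race indicators — an appropriate model for a
   handful of predictors. The penalty defaults to `penalty = 1` (the
   `glmnet` lambda on standardized inputs) and is configurable; results are
   insensitive to it over a wide range because the predictor set is small.
   Age is standardized with training-fold statistics so held-out encoding
   never sees test data.
3. **Ensemble**: the probability-level combination
   $$p = \frac{\mathrm{AUC}_1\, p_{\text{lang}} + \mathrm{AUC}_2\,
   p_{\text{demo}}}{\mathrm{AUC}_1 + \mathrm{AUC}_2},$$
   with weights equal to each model's training-set AUC (computed in-sample
   on the training fold; an inner-CV weight estimate would be less biased
   but is not the default, matching the definition above).

Discrimination is measured by the AUC — the probability that a random case
outscores a random control, ties counting one half.

## Significance and false-discovery control

* **Model vs model** (language vs demographics; ensemble vs demographics):
  a Monte-Carlo *paired sign-flip* permutation test. Under the null that
  the two models are exchangeable, each participant's pair of out-of-fold
  scores can be swapped; each of the 100,000 iterations swaps each pair
  independently with probability one half and recomputes the AUC
  difference. Two-sided.
* **Model vs chance**: a label-permutation test; one-sided (greater),
  matching the directional claim "predictable beyond chance".
* Both tests use add-one smoothing, $p = (\#\{\text{as extreme}\} + 1) /
  (n_{\text{iter}} + 1)$, so p-values are never exactly zero and
  Benjamini–Hochberg adjustment downstream behaves correctly.
* **Families**: BH is applied across conditions separately within each of
  the three comparison types, and, in the marker scan, across the 200
  topics within each condition. The choice of family is a convention; it is
  recorded in the outputs.

What the permutation test permutes is a genuine design choice: for paired
model comparisons the sign-flip null is standard and respects the pairing;
for the chance comparison the label permutation is exact. Both are exposed
as separate functions.

## Marker identification

Each topic is evaluated alone: (1) the AUC of the raw usage score (any
monotone univariate model gives the same value, so no model is fitted);
(2) the out-of-sample AUC of ridge logistic over demographics; (3) the same
with the topic added (standardized with training-fold statistics).
Significance of (3) vs (2) uses the paired sign-flip test, BH-adjusted
across topics. A topic's *direction* is +1 when cases use it more than
controls.

The risk contrast is summarized as a **quartile likelihood ratio**:
participants are split into quartiles of the topic score (ties broken by
stable participant order — relevant for zero-inflated scores), and the
ratio of maximum-likelihood condition probabilities (sample means) between
the top and bottom quartile is reported with a percentile 95% CI from
10,000 bootstrap resamples. Resampling is performed *within* each quartile,
conditioning on the observed quartile membership; a bottom-quartile
resample with no cases contributes $+\infty$, so the upper bound is
reported as $+\infty$ whenever the 97.5th percentile is infinite — the
"[3.16, inf]" output pattern. Resamples in which both quartiles have zero
cases (possible only at very low prevalence) carry no information about the
ratio and are dropped. When the *observed* bottom quartile has no cases the
point estimate is $+\infty$ and every within-quartile resample is infinite
too; the reported lower bound then uses a continuity-corrected denominator
(half a case in the bottom quartile), giving a conservative finite
"at least this large" bound. The implementation draws the within-quartile
resample means directly as scaled binomials, which is exactly equivalent to
resampling the binary vectors. Re-quartiling each resample is available as
an option but is not the default, because conditioning reproduces the
infinite-upper-bound behavior of the reported intervals.

The condition-by-topic summary is the **signed topic-expression matrix**
with entries $\mathrm{direction} \times (\mathrm{AUC}_{\text{topic}} -
0.5) \in [-0.5, 0.5]$; rows (conditions) are ordered by agglomerative
hierarchical clustering (average linkage, Euclidean distance — both
configurable; the transform and the linkage are conventions chosen here,
since "predictive strength colored by direction" admits several encodings).

## The synthetic cohort generator

The generator emulates the *statistical structure* the pipeline assumes —
not real social-media language. Per participant $u$:

* a topic mixture $\theta_u \sim \mathrm{Dir}(\alpha_{\text{mix}})$ over
  $K_{\text{true}}$ topics;
* each word: topic $\sim \mathrm{Cat}(\theta_u)$, word $\sim
  \mathrm{Cat}(\phi_{\text{topic}})$, with $\phi$ rows drawn once from
  $\mathrm{Dir}(\alpha_{\text{topic}})$ over a synthetic vocabulary
  (`w001`, ...);
* words are partitioned uniformly at random into posts (post boundaries
  matter only for bigrams);
* demographics: age uniform over a range, sex and race categorical with
  proportions defaulting to a typical urban-cohort composition (76%
  female; race 71/23/2/4%);
* condition labels: $P(y=1) = \mathrm{logistic}(\beta_0 + \beta^\top
  \theta_u + \gamma^\top x_u)$ with configurable planted topic and
  demographic effects; each label is drawn by comparing one uniform to the
  probability, so raising an intercept at a fixed seed can never lose a
  case (a monotonicity the tests exploit).

Default scales: 1,000 participants, 600 words each over 20 posts, a
500-word vocabulary, 20 true topics. These mirror a scaled-down cohort: a
real 999-participant corpus averages ~20,000 words per participant over a
20,000-gram vocabulary; scaling both the per-participant word count and the
vocabulary by roughly the same factor keeps per-word counts, and hence
gram-level signal-to-noise, in a realistic regime while keeping simulation
studies fast. Topic-word concentration defaults to 0.01 (topics concentrate
on a few dozen words — heavy-tailed word distributions typical of fitted
social-media topics) and mixture concentration to 0.1 (participants use few
topics heavily, the sparse usage regime LDA fits to personal corpora
exhibit). Generated corpora satisfy the ≥500-words-per-participant
adequacy filter by construction at these defaults.

What the generator does **not** emulate: real lexical statistics (Zipf
tails beyond the Dirichlet's, emoji, code-switching), temporal posting
dynamics, label noise in diagnoses, or correlated conditions. Passing
recovery tests on generated data therefore demonstrates correctness of the
machinery and the calibration of its statistical tests, not performance on
real cohorts. Note also that a planted coefficient on a topic *proportion*
bounds the achievable discrimination: with 20 topics, a coefficient of +3
on one mixture component yields a Bayes-optimal AUC of only about
0.56–0.60 depending on sparsity, so moderate planted effects are
intrinsically hard-to-significant signals — a property of the outcome
model, not of the estimator.

## Numerical choices and degenerate inputs

* The ≥500-word adequacy filter is inclusive (`total_words >= 500`); the
  threshold is a parameter. A minimum-posts filter (default 20, off by
  default in the pipeline) is also available.
* Monte-Carlo p-values are add-one smoothed (see above); the smallest
  attainable p is $1/(n_{\text{iter}}+1)$.
* A constant (degenerate) topic in the marker scan is reported with AUC
  0.5, p = 1, and a `degenerate` flag rather than an error.
* A training fold with a single class is skipped and recorded; conditions
  with fewer than 30 cases (or controls) are excluded before evaluation.
* Gram-frequency ties in ranking and word ties in topic summaries are
  broken lexicographically in the C locale, making outputs
  locale-independent.
* `fwer_select` assigns zero-variance grams p = 1 rather than dropping
  them, so index bookkeeping is stable across folds.
* ERT node size: trees are grown to purity by default, following the
  original algorithm. For weak signals, a larger `min_node_size` (10–50)
  yields smoother leaf probabilities and often slightly better held-out
  AUC; the evaluation defaults keep the canonical setting and expose the
  knob.

## Problem sizes used by the validation studies

The bundled studies (test suite and acceptance script) run at the
generator's default scale: 1,000 participants × 600 words, 20 true and 20
fitted topics, 500 selected grams, 10-fold cross-validation, 2,000
permutation iterations, with 100 Gibbs sweeps for the topic model — sizes
at which each replicate's conclusions are stable while a multi-replicate
study completes in minutes. Calibration studies (permutation type-I error,
bootstrap CI coverage) use smaller per-replicate sizes (n = 200–400) with
hundreds of replicates, which is the right trade-off for estimating
rejection rates rather than effect sizes.

## Known limitations

* Topic scores are a bag-of-words summary; no sequence or recency
  information is used (posts are equally weighted regardless of age).
* The FWER selection statistic tests linear association of gram frequency
  with the label; purely non-monotone gram effects would be missed at the
  selection stage (the trees could still exploit them if selected).
* The quartile ratio conditions on observed quartile membership; its CI
  does not account for uncertainty in the quartile boundaries themselves.
* The synthetic generator's independence assumptions (words i.i.d. given
  the mixture; conditions independent given covariates) are idealizations;
  see above for what passing tests does and does not show.
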