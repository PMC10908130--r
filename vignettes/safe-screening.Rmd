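---
title: "Simulating the SAFE stopping heuristic for active-learning screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the SAFE stopping heuristic for active-learning screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safescreen)
```

## The problem

Title/abstract screening for a systematic review asks a human to sort
thousands of bibliographic records into relevant and irrelevant.
Active-learning tools reorder the unscreened pool so that likely-relevant
records are presented first, which concentrates the relevant records in the
early part of the screening sequence — but it leaves the reviewer with a
harder question: *when is it safe to stop?* Stop too early and relevant
records are missed; stop too late and the time saved by prioritization is
spent reading irrelevant abstracts.

`safescreen` implements the SAFE procedure — a conservative, four-phase
stopping heuristic that composes several simple rules instead of relying on
any single one — as a fully simulated, deterministic pipeline: a labeled
corpus stands in for the reviewer (an *oracle*, optionally with a
false-negative error rate), so every phase, rule and failure mode can be
exercised and measured at desk scale.

## The four phases

1. **Screen a random training set.** A seeded random (or date-stratified)
   sample of $n_1 = \max(\texttt{phase1\_min},\ \lceil \texttt{phase1\_fraction}
   \cdot T \rceil)$ records is labeled. If either class is still missing
   afterwards, random screening continues until at least one relevant and
   one irrelevant label exist. From the $t$ training labels with $RR_t$
   relevant, the fraction of relevant records is
   $FRR_t = RR_t / t$, and
   $\widehat{RR}_T = \lceil FRR_t \cdot T \rceil$
   crudely estimates the total number of relevant records. The ceiling
   (rather than rounding) is deliberate: the estimate sets a screening
   floor, and the procedure is conservative by design.
2. **Active learning.** A cheap lexical model (TF-IDF features with
   multinomial naive Bayes or logistic regression) is refit after every
   label, and the top-ranked unscreened record is presented next. Screening
   stops at the first record where **all four** conditions hold:
   every key paper has been labeled relevant; at least
   $\texttt{rrt\_multiplier} \times \widehat{RR}_T$ records have been
   screened; at least $\lceil \texttt{min\_fraction} \cdot T \rceil$
   records have been screened; and the last `window` decisions in this
   phase were all irrelevant. Counting for the two floors is cumulative
   across phases 1–2: the training labels are screening effort, and
   excluding them would charge the reviewer twice.
3. **Model switch.** The remaining pool is re-ranked by a structurally
   different model family trained on all labels so far, to catch records a
   lexical model systematically under-ranks (concept ambiguity). The phase
   stops when `window` consecutive decisions in *this phase* are
   irrelevant.
4. **Quality check.** An independent, error-free second screener revisits
   the records previously labeled irrelevant, ranked by a simple model
   trained on pseudo-labels: the 10 highest-ranked records of the final
   phase-3 ranking are treated as relevant, the 10 lowest as irrelevant.
   Relevant finds flip the record's final label. The same window rule
   stops the phase.

All rule parameters sit in `stopping_config()` and are deliberately
user-configurable; the defaults (1% / 50-record training phase, factor 2 on
the estimate, 10% minimum fraction, 50-record window) are customary example
settings, not universal constants.

### Design choices in the rules

* **Criteria are evaluated after every label**, and stopping takes effect
  at the first satisfying record. Batch evaluation would overshoot by an
  amount that depends on batch size.
* **The consecutive-irrelevant streak is phase-scoped.** Each phase
  re-ranks with a different model, so a streak accumulated under the
  previous model says nothing about the new ranking. Phases 3 and 4 use the
  same window rule, likewise scoped.
* **Recall-plateau inspection (`plateau_reached()`) is advisory only.** It
  flags when the trailing `plateau_window` viewed records added at most
  `plateau_slope_max` new relevant records per record, but it never gates
  stopping by itself — visual plateau detection is a prompt to check the
  binding rules, not a rule.
* **Census fallback.** On small corpora the pool can empty before the
  four-fold rule is met; the engine then stops with a `census` mark and
  reports which conditions were unmet rather than erroring.
* **Phase-1 stop rule.** The procedure requires both a minimum training
  size *and* at least one record of each class; the engine implements the
  conjunction (continue past $n_1$ until both classes are present), the
  stricter of the two readings. $\widehat{RR}_T$ is always computed from
  the full final phase-1 set.
* **Stratified phase-1 selection** takes the $k = \lceil n_1/10 \rceil$
  oldest and $k$ newest records by year plus seeded random intermediates;
  records with a missing year are eligible only for the random stratum.
  The estimator's unbiasedness property is asserted only under pure random
  sampling, since date stratification can bias the prevalence estimate.

## Ranking models

**Simple lexical family.** TF-IDF in a fixed dialect: unigrams over
lowercased alphanumeric tokens, minimum document frequency 1, smoothed IDF
$\log((1+n)/(1+df)) + 1$, L2-normalized rows. Two classifiers:

* `naive_bayes` (default): multinomial scoring over TF-IDF mass with
  *class-balanced* smoothing — the class-conditional term distribution is
  estimated from the class centroid, so a term unseen in both classes
  contributes exactly zero. Plain Laplace smoothing over pooled class mass
  gives unseen terms a positive log-odds whenever the irrelevant class has
  more training mass, which makes any document with unusual vocabulary
  look relevant; scoring absence of evidence that way would hand phase 2
  the very records phase 3 exists to find.
* `logistic`: ridge-penalized kernel logistic regression (linear kernel
  plus intercept, IRLS). The kernel form keeps the fit well-posed at the
  contract's minimum training set of one record per class, where standard
  GLM solvers refuse to run.

**Alternative family (`svd_kernel`).** The model-switch phase needs a
second inductive bias, not a second accuracy benchmark. Every document is
embedded by truncated SVD of the corpus TF-IDF matrix (computed via the
eigendecomposition of the $n \times n$ document Gram matrix, so cost is
independent of vocabulary size; 32 components by default), and scored by
the difference of mean RBF-kernel similarities to the labeled relevant and
labeled irrelevant embeddings. The bandwidth is the median
nearest-neighbour distance among labeled embeddings — a local scale, so
the scorer responds to cluster structure rather than the global spread.
Documents that resemble neither the labeled relevants nor the labeled
irrelevants score near zero, *above* the mass of typical irrelevant
records; that is precisely the behaviour that surfaces
divergent-vocabulary relevants. The family is deterministic and needs no
pretrained weights; a genuinely neural model can be plugged in through
`register_model_family()`.

**Feature extractors are fitted on the whole corpus; labels only ever
drive the classifier.** This is standard practice in screening tools, and
it is also the only way a record whose vocabulary never appears in the
labeled set can receive a non-degenerate embedding.

**Phase-4 pseudo-labels** come from the final phase-3 model's ranking over
*all* records (labeled included). Ranking only the residual unlabeled pool
would, after a successful screen, put noise at both ends and train the
quality-check model on nothing; ranking everything puts the confirmed
relevants at the top, so the pseudo-relevant seed set carries the
strongest available signal. With fewer than 20 ranked records the split
degrades to halves with a warning.

## The synthetic corpus generator

`generate_corpus()` emulates the statistical structure the procedure
assumes, not natural language. Documents are token streams over an integer
vocabulary rendered as pseudo-words:

* a **Zipf background** (default 20,000 terms, exponent 1): every document
  carries some rare, training-unseen terms, as real titles and abstracts
  do — without this, "has unusual words" would itself separate the
  classes;
* a **main relevant topic** (default 40 terms, disjoint from the
  background): relevant records mix topic and background tokens with
  weight $w = \texttt{separability}/(1+\texttt{separability})$, so
  `separability = 0` makes the classes exactly indistinguishable and the
  default 3 gives a strongly separable corpus;
* two **irrelevant subtopics** (15% of irrelevant records each): realistic
  corpora are not homogeneous off-topic noise;
* a **hard relevant subpopulation** (`hard_fraction` of the relevant
  records): their topic tokens come from the *union* of the two irrelevant
  subtopics. Their vocabulary is exactly what a lexical model has learned
  to score as irrelevant — only the co-occurrence of both subtopics in one
  document marks them, which a bag-of-terms ranker cannot see but a latent
  co-occurrence embedding can. This operationalizes concept ambiguity and
  gives phase 3 something only it can find. Hard records share no terms
  with the main relevant topic and are never key papers.

Class counts are exact (`round(prevalence * n_records)` relevant,
`round(hard_fraction * n_relevant)` hard), not binomial, so tests know the
true $R$ for recall denominators. Key papers are drawn from the main-topic
relevants only, reflecting the concern that expert-nominated key papers
are unrepresentative of the full relevant set. Years are uniform over
`year_range`; `inject_noise()` adds missing abstracts and near-duplicates
to exercise input validation. Identical seeds give byte-identical corpora.

Default study conditions, chosen once: `n_records = 1000`,
`prevalence = 0.05` (a realistic screening prevalence), `separability = 3`,
`hard_fraction = 0` (the hard subpopulation is opt-in; the model-switch
analyses use 0.2), `n_key_papers = 3`, `doc_length_mean = 60` tokens
(title plus abstract), `year_range = 1990–2024`, noise rates 0.

What passing tests on this generator do **not** show: performance on real
abstracts (no grammar, no synonymy, no citation structure), behaviour
under prevalences far below 1%, or the cost/benefit of a genuinely neural
phase-3 model. They do show that the rules, the estimator, the phase
mechanics and the metrics behave as specified on corpora whose ranking
geometry matches the procedure's assumptions, in both the separable and
the indistinguishable regime.

## Oracles, determinism and degenerate inputs

The first screener is either perfect or noisy; the noisy mode flips a
truly relevant record to irrelevant with probability
`false_negative_rate` (default 0.10, the rate human screeners are commonly
observed to miss) and never flips irrelevant records. Flips are
deterministic per record (seed + record id), independent of presentation
order, and recorded, so the phase-4 soundness property — every recovered
record is a previously flipped one — is checkable on every run. The
phase-4 second screener is always error-free: the quality-check phase
exists to catch first-screener errors, and simulating it with the same
noisy oracle would make it vacuous.

A single `seed` expands through `derive_seed()` into per-component seeds
(corpus, sampling, models, oracle, baselines), so one integer reproduces a
run bit for bit; the test suite asserts byte-identical logs and metrics
JSON. Ties in every ranking break by ascending record id. Degenerate
inputs have defined behaviour: empty corpora and all-irrelevant corpora
are rejected at validation; a corpus the oracle can never label relevant
raises a "degenerate corpus" error in phase 1; `window = 1` runs; an empty
phase-3 pool records an immediate census stop.

## Metrics

`recall_curve()` cumulates relevant finds per decision.
`compute_metrics()` reports recall at stop, the loss (missed relevant
count), and work saved over sampling at the achieved recall,
$WSS = (T - n_{\text{viewed}})/T - (1 - \text{recall})$, with
$n_{\text{viewed}}$ counting screening *decisions* (a phase-4 re-screen is
charged as effort). WSS is also reported at recall 0.95 when that level is
reached, for comparability across runs. The random-order baseline (the
expected number of views a uniform random order needs to match the
achieved recall) is a seeded Monte-Carlo estimate reported with its
standard error; at full recall it is validated in the tests against the
closed form $R(T+1)/(R+1)$ for the expected position of the last relevant
record. `prisma_counts()` emits the identified / screened-per-phase /
included / excluded / never-viewed tallies, which always conserve:
identified = included + excluded + never viewed.

## Problem sizes in the test suite

The suite exercises the stopping rules against a brute-force scan on
10,000 randomized logs ($T \le 200$), estimator calibration on 2,000
random training sets from a $T = 5{,}000$, $R = 250$ corpus, end-to-end
runs at $T = 1{,}000$, the efficiency-vs-random property over 50 replicate
corpora, and the phase-3/phase-4 mechanisms over 20 seeds each — sizes
chosen so the whole suite runs comfortably on a laptop while keeping the
Monte-Carlo error small relative to the asserted margins.

## Limitations

The procedure itself is heuristic: none of the four conditions estimates
recall, and the stopping point carries no statistical guarantee — that is
the cost of rules a non-specialist can apply. The simulation inherits the
generator's idealizations listed above; in particular, lexical
separability is the *definition* of the easy regime here, whereas on real
corpora it is an empirical question. The hypergeometric
`upper_bound_relevant()` is provided as an optional conservative
alternative to the crude point estimate and is off by default; richer
recall-estimation methods from the stopping-rule literature are
deliberately out of scope.
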