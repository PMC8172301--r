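---
title: "Pattern-similarity prediction of in-hospital mortality from care trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-similarity prediction of in-hospital mortality from care trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careseq)
library(dplyr)
```

`careseq` predicts a binary in-hospital outcome from the *shape* of a
patient's care trajectory rather than from a flat bag of diagnoses. This
vignette explains the model and its assumptions, the parameters that matter,
the numerical choices, what the synthetic generator does and does not
emulate, and the design decisions taken where the protocol left the design
open.

## 1. From stay records to trajectories and contexts

The input is one row per event code per stay:
`patient_id, order_index, code, code_system, sex, age, outcome`. The
`order_index` is an abstract temporal rank (a month number, a stay rank):
decoupling the miner from calendar parsing keeps the engine applicable to
any discharge database extract. Codes sharing an `order_index` form one
itemset; itemsets ordered by rank form the trajectory. Stays can be
restricted to a disease area with `filter_relevant_stays()`; which code
prefixes count as relevant is configuration, not hard-coded, because code
lists differ by country and coding system. A patient whose every stay is
filtered away is dropped rather than kept as an empty sequence — all
downstream definitions require non-empty sequences.

Covariates are discretized into the classes used for sub-population
modelling: age 45–65 versus >65 (boundary in the lower class, matching the
class labels), and stay count ≤5 versus >5 (likewise). Patients at or below
the inclusion age of 45 are excluded. The context hierarchy is every
conjunction over sex, age class and stay class with each attribute fixed or
free — 3 × 3 × 3 = 27 contexts including the fully free *general* context.
Contexts are never silently deleted: cells below a configurable minimum size
or with too few events per outcome class are *flagged* excluded and listed,
because which cells are too sparse is a property of the data at hand, not of
the method.

## 2. Contextual mining and maximal filtering

Support is document frequency: the fraction of a context's patients whose
trajectory embeds the pattern, regardless of how often it occurs within one
patient. Embedding means itemset containment at strictly increasing
positions, checked by a greedy earliest-match scan (exact for this
relation). Mining is recursive prefix projection in the PrefixSpan style:
each frequent prefix restricts the database to the suffixes after its
earliest match, and candidate extensions are counted there. The default
grows single-item itemsets only — discharge trajectories are effectively one
code per stay position — but itemset growth (`allow_multi_item = TRUE`)
is supported so that multi-code stays can be mined too.

Two numerical choices matter here:

* **Boundary-exact support.** The required patient count is
  `ceil(minsup × n)` computed with a rational guard, so a threshold of 2/3
  on 12 patients needs exactly 8 — floating-point noise cannot flip a
  frequency decision at the boundary.
* **Canonical ordering.** Mined patterns are ordered by support descending,
  then pattern string. Feature columns downstream inherit this order, so a
  rerun reproduces the same design matrix column for column.

`min_support` defaults to 0.01: trajectories are short and heterogeneous,
so informative multi-stay patterns only appear at low supports. A resource
cap (`max_patterns`) trips with guidance instead of flooding memory when the
threshold is set too low for the vocabulary.

Frequent sets are then reduced to **maximal** patterns — those not embedded
in any other retained pattern. Non-maximal patterns carry no extra embedding
information and produce nearly collinear similarity columns; dropping them
is a variance-reduction step, not an approximation.

## 3. Token-level similarity

Trajectory–pattern similarity is computed on *token* texts: one token per
event code, itemsets flattened in lexicographic order. Character-level
distances would conflate code spelling (I21 versus I25 differ by one
character) with sequence structure; at token level two codes are simply
equal or different, which is the faithful reading of comparing patterns of
care.

Nine measures in three families are implemented from their standard
definitions: Levenshtein, optimal string alignment (adjacent transposition,
no reuse), unrestricted Damerau–Levenshtein, and longest common *substring*
(contiguous, per its name; distance `|a|+|b|−2·LCSstr`); q-gram (L1 gap
between q-gram count profiles), Jaccard and cosine on q-gram sets/counts;
Jaro and Jaro–Winkler. Normalization to [0, 1] is per family: the edit
distances divide by `max(|a|,|b|)` (the common-substring distance by
`|a|+|b|`), the q-gram distance by total profile mass, and the remaining
measures are already normalized. Degenerate inputs are made total
explicitly: two empty texts (or two empty q-gram profiles) are maximally
similar; one empty against one non-empty scores 0.

Defaults: `q = 2` — trajectories are short, so longer grams would empty most
profiles; Jaro–Winkler prefix scale 0.1 with cap 4, the universal
convention. Discretization cuts at 0.4 and 0.6 (low/medium/strong), with the
boundary values in the upper class.

## 4. Modelling, selection, validation

Patients are split once, 2/3 internal : 1/3 external, before any modelling;
the external third is untouched until final validation, and mining itself
runs on internal patients only so no pattern information leaks across the
split. Internal validation is repeated stratified holdout (default 5
rounds, 2/3 training): in each round the training part is balanced by
uniformly undersampling survivors (every death is kept), the model is
fitted, and metrics are taken on the unbalanced test part with hard
predictions at 0.5 — the natural threshold after balanced training.
Averaging over rounds is what makes the reported "predicted deaths" counts
fractional. The number of rounds and the aggregation (mean) are
configurable choices; the protocol this package follows did not fix them.

The six families use standard fits behind one scorer interface that always
returns a death probability: Gaussian/categorical naive Bayes, k-NN (k = 5,
vote shares as probabilities), a cost-complexity-pruned classification
tree, unpenalized logistic regression, a radial SVM with built-in
Platt-style probability calibration, and a single-hidden-layer neural net
(size `max(3, p)`, weight decay 0.01). Seeds are threaded explicitly
through split, balance and fit, so every configuration is reproducible end
to end. Random forests, boosting and hyperparameter search are deliberately
out of scope.

Model selection uses the maximal-vector (Pareto) rule on AURC ↑,
F-measure ↑, error rate ↓: a configuration survives unless some other is at
least as good on all three and strictly better on one. The three criteria
can genuinely disagree, so the full non-dominated front is reported; when a
single nomination is needed the front is ordered lexicographically by the
criteria (then by configuration name), a deterministic linear extension of
the dominance order. The criteria list is configurable up to all seven
computed metrics. External validation reports AURC and the Brier score on
the untouched split, unbalanced as observed.

## 5. The synthetic generator: what it emulates, what it does not

`generate_cohort()` emulates the *structure* of a discharge cohort so that
every stage has testable ground truth: covariates (60% men, 45% aged
45–65), stay counts `4 + min(Pois(1.2), 6)` — mean ≈ 5, range 4–10,
straddling the ≤5/>5 boundary — a 16-code vocabulary, and per-context risk
patterns planted as ordered subsequences with noise codes interleaved. The
default plants one four-code trajectory (chest pain → angina → infarction →
heart failure) in 30% of patients. Death is Bernoulli with
`logit P = −9 + 12 · maxsim`, where `maxsim` is the realised Levenshtein
similarity between the generated trajectory and the applicable risk
patterns. Putting the outcome downstream of *similarity* (not of a planted
flag) places the featurization step on the causal path: a bug in the
distance code would visibly destroy recovery. The intercept/slope pair was
fixed at design time to give a realistic sub-20% death prevalence while
keeping the strong-signal scenario unambiguous (population-level AURC well
above 0.9); the matching null scenario uses slope 0 and intercept
`qlogis(0.14)`, reproducing a ~14% prevalence.

What the generator does **not** emulate: calendar time (no seasonality, no
inter-stay gaps), comorbidity structure, coding noise correlated with
severity, competing risks, or context-specific outcome models beyond the
risk-pattern table. Passing tests therefore demonstrate that the machinery
recovers known structure under clean sampling assumptions — they do not
demonstrate clinical validity on real claims data, where signal strength,
confounding and code quality are empirical questions.

Test and verification scales were chosen to exercise the asymptotics
without waste: oracle equivalence on hundreds of micro-databases (≤12
patients, 4–6 codes) where exhaustive enumeration is feasible; support
recovery at n = 500/2,000/8,000; end-to-end discrimination on
1,500-patient cohorts (≈1,000 internal / 500 external), where binomial
noise on AURC is small against the [0.4, 0.6] null band and the 0.9
strong-signal bound, across 10 seeds.

## 6. Known limitations

* The miner is exact but in-memory and single-threaded; vocabularies of
  thousands of codes at 1% support will need the resource cap raised and
  patience, or a pre-filter to a disease-area code list.
* Patterns carry no time gaps; two stays years apart match a pattern as
  readily as two consecutive ones.
* k-NN probabilities are vote shares over k = 5 neighbours, hence coarse;
  its Brier scores are correspondingly weak, which mirrors its poor rank in
  practice.
* Context models are fitted independently; there is no borrowing of
  strength across the hierarchy.
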