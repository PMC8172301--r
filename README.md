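# careseq

Predicting a binary in-hospital outcome — death during a stay — from
administrative care trajectories. `careseq` implements the full protocol for
cohorts such as acute coronary syndrome patients in a hospital discharge
database: it turns coded stay records (ICD-10 or DRG) into per-patient event
sequences, mines **contextual maximal frequent sequential patterns**,
converts each trajectory into a **pattern-similarity feature vector** under
nine token-level string measures, trains six classifier families over every
(model, similarity, encoding) configuration, selects combinations by
**Pareto-optimal discrimination**, and validates externally with ROC area
and the Brier score. A synthetic cohort generator with planted patterns and
known ground truth makes every stage testable without access to restricted
hospital data.

It is aimed at biostatisticians and epidemiologists working with
claims/discharge data who want sequence-aware predictors without deep
learning: the feature space is a small set of interpretable care-path
patterns per sub-population.

## The method

A trajectory is an ordered list of itemsets of event codes,
`S = ⟨it_1, …, it_p⟩`. A pattern `P` is *supported* by a patient when `P`
embeds in their sequence (itemset containment at strictly increasing
positions). Within a context `c` (a conjunction of covariate classes over
sex, age class 45–65 / >65, and stay count ≤5 / >5),

    support_c(P) = #{patients in c whose trajectory embeds P} / #c

Patterns with `support_c(P) ≥ minsup` are mined by a PrefixSpan-style
recursive prefix projection, then reduced to the **maximal** ones (not
embedded in any other frequent pattern) to avoid collinear features.

For a patient with trajectory `T_P` and context patterns `s_1^c, …, s_k^c`,
the feature vector is

    sim_P^c = ( sim(T_P, s_1^c), …, sim(T_P, s_k^c) )

where `sim` is one of nine token-level string similarities in three
families: edit-based (longest common substring, Levenshtein, optimal string
alignment, Damerau–Levenshtein), q-gram based (q-gram, Jaccard, cosine) and
heuristic (Jaro, Jaro–Winkler). Similarities enter models either continuous
or discretized (low < 0.4 ≤ medium < 0.6 ≤ strong). Six families — naive
Bayes, k-NN, classification tree, logistic regression, SVM, neural net —
over nine measures and two encodings give 108 configurations per context;
the best (model, similarity) combination is the maximal-vector (Pareto)
front on AURC, F-measure and error rate, and the selected models are scored
once on an untouched external split.

## Worked example

```r
library(careseq)
library(dplyr)

coh <- generate_cohort(cohort_config(n_patients = 1500, seed = 1))
coh
#> Synthetic cohort: 1500 patients, 17.2% deaths, 435 planted

db <- discretize_covariates(coh$db)
study <- run_study(db,
                   families = c("SVM", "LR"),
                   measures = c("levenshtein", "jaro"),
                   encodings = "continuous",
                   mining = mining_config(0.1),
                   repeats = 3, seed = 1, general_only = TRUE)

tidy(study$patterns) |> head(5)
#>   context_label pattern_str               support n_items
#> 1 general       <(R07) (I20) (I21) (I50)>   0.293       4
#> 2 general       <(Z51)>                     0.243       1
#> 3 general       <(I48)>                     0.241       1
#> 4 general       <(I10)>                     0.237       1
#> 5 general       <(I63)>                     0.232       1

tidy(study) |> select(family, measure, aurc, error_rate, external_aurc, brier)
#>   family measure      aurc error_rate external_aurc  brier
#> 1 SVM    levenshtein 0.974     0.0821         0.971 0.0709
#> 2 LR     levenshtein 0.972     0.0791         0.964 0.0674
#> 3 SVM    jaro        0.967     0.0771         0.965 0.0734
#> 4 LR     jaro        0.962     0.0911         0.952 0.0744
```

The miner recovers the planted four-code risk trajectory
`<(R07) (I20) (I21) (I50)>` at a support close to its 0.3 planting rate
(the singletons are frequent filler codes). Internally, the SVM with the
token-level Levenshtein similarity discriminates death with AURC 0.97, and
the external AURC of 0.97 with a Brier score of 0.07 confirms the model
generalizes to the held-out third of the cohort. `glance(study)` returns the
nominated best combination; `autoplot(study)` plots the configuration sweep.

On real stay records, start from `read_stay_records()`,
`filter_relevant_stays()` (e.g. prefixes `I20`–`I25`, `R07`, `I50`) and
`build_trajectories()`, then proceed identically.

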