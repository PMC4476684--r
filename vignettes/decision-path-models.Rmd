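---
title: "Personalized decision-path models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized decision-path models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decisionpath)
```

## The problem and the model

Clinical risk models are usually *population* models: one decision tree (or
regression) is fitted to a training cohort and applied unchanged to every
future patient. A *personalized* (lazy) alternative defers model construction
until the test patient is known: their observed features steer the search, so
the model is built from, and for, exactly the kind of individual being
predicted.

The model class here is deliberately minimal: a **decision path** is a single
conjunction of features,

$$S: V_1 = v_1 \wedge V_2 = v_2 \wedge \dots \wedge V_J = v_J,$$

where every value $v_j$ is the test patient's own value, together with a
probability vector $\theta$ over the binary outcome $T$. The parameters come
from the training individuals matching $S$, smoothed by the **BDeu**
posterior mean

$$\theta_k = \frac{\alpha_k + N_k}{\alpha + N}, \qquad \alpha_k = \frac{\alpha}{K},$$

with $\alpha$ the *prior equivalent sample size* (`pess`, default 1 -- the
non-informative setting used throughout; every probability stays strictly
inside $(0,1)$, so even a one-patient subgroup never predicts certainty). A
decision path is exactly one probabilistic IF-THEN rule, which is why
`export_rule()` can print any fitted model in a line.

## Growing a path

`grow_path()` performs greedy forward selection. At each step, the candidate
set is every predictor not yet on the path whose value is *observed* in the
test patient -- missingness in the patient is handled by simply never
proposing those variables. Each candidate $V$ is scored by splitting the
current matching subgroup $D$ into $D_{tmp}$ (individuals also matching
$V = v$) and $D - D_{tmp}$; both halves always enter the score so that every
candidate is judged on the same set of individuals. Growth stops when no
candidate remains, when every remaining candidate's matching half would be
empty, or when the subgroup is pure in the outcome.

Three split criteria are available:

* **`bay`** -- the two-sample Bayesian score: the log marginal likelihood of
  the outcome values in the two halves under independent
  Dirichlet--multinomial models with prior mass $\alpha_{jk} = \alpha/K$ per
  cell,
  $$\sum_{j=1}^{2}\Big[\log\Gamma(\alpha_j) - \log\Gamma(N_j+\alpha_j)
    + \sum_k \big(\log\Gamma(N_{jk}+\alpha_{jk}) -
      \log\Gamma(\alpha_{jk})\big)\Big],$$
  computed entirely in log-gamma space (no factorials are ever formed).
  Averaging over parameters penalizes splits that small samples cannot
  support.
* **`ig`** -- information gain: parent entropy minus size-weighted child
  entropies, in bits.
* **`auc`** -- a leave-one-out AUC: within each half, every individual
  receives the BDeu probability estimated from the remaining members of that
  half (a closed form, since all same-class members of a half share one
  value); the pooled predictions are ranked against the true labels with the
  Mann--Whitney statistic, ties earning half credit. Binary outcomes only.

## Pruning, and why two scores appear in the trace

After growth, `prune_path()` keeps the prefix ending at the step whose
*recorded* score is maximal (ties go to the shortest prefix -- the simpler
model). The subtlety is what to record. The subgroup-level log marginal that
drives selection shrinks in magnitude with the subgroup: a split of 1,000
patients scores around $-600$, a split of 4 patients around $-5$. Recording
it verbatim makes the argmax land on the deepest step essentially always,
which silently disables pruning and turns the learner into an unpruned lazy
tree; we implemented and measured that variant first, and its cross-validated
performance collapses exactly as overfitting predicts. The package therefore
records, for the path after each step, the same criterion evaluated **on the
full training cohort** partitioned into path-matching and non-matching
individuals -- the posterior score of the path itself, conditioned on the
same $N$ individuals at every depth. Selection remains subgroup-based (all
candidates within a step see the same individuals); recording is path-based
(all depths see the same individuals). With this convention pruning behaves
as intended for all three criteria: paths on cohorts with planted signal
prune back to the informative prefix, typically one to three conjuncts, with
support in the hundreds rather than single digits.

Degenerate candidates are resolved as follows: a candidate no remaining
individual matches is skipped (selecting it would strand the search); a
candidate *every* remaining individual matches is scoreable (its
non-matching half is empty, and an empty sample has marginal likelihood 1,
gain 0, or AUC from the matching half alone) but cannot shrink the subgroup,
and because its recorded path score repeats the previous step's, the
shortest-prefix tie rule removes it again. Missing values in *training*
rows never satisfy a conjunct, so such rows fall to the non-matching side;
the data's own description of an individual decides what they match, and no
imputation is attempted.

## The population comparator

`fit_population_tree()` is the population benchmark: top-down recursive
multiway splitting on information gain ("deviance" splitting), each variable
used at most once per path, children covering the variable's full domain,
training rows missing the split variable routed to the child that received
the most rows (the same child later used to route missing values at
prediction). Splitting proceeds even through zero-gain ties (an XOR-style
interaction is only visible one level down) and stops at purity, exhausted
variables, `max_depth`, or the `min_leaf` floor. Leaves are BDeu-smoothed
with the same `pess`. Bottom-up pruning collapses an internal node whenever
the Dirichlet--multinomial log marginal of its pooled counts is at least the
sum of its children's marginals -- the multiway analogue of the two-sample
Bayesian score, with ties collapsing toward the simpler model. This is a
standard greedy tree, not a port of any particular commercial implementation;
its binary-split, cost-complexity-pruned cousins will differ in detail.

## Preprocessing

Continuous predictors are discretized by recursive entropy minimization with
an MDL stopping rule: the best cut (scanning every midpoint between adjacent
distinct values; boundary-point theory guarantees this finds the optimum) is
accepted iff

$$\text{gain} > \frac{\log_2(N-1)}{N} +
  \frac{\log_2(3^k - 2) - (kH - k_1H_1 - k_2H_2)}{N},$$

then each side is processed recursively. Bins are half-open $(c_i, c_{i+1}]$
-- a value equal to a threshold falls in the lower bin -- and a variable with
no accepted cut becomes a flagged constant bin that no learner will ever
split on. Within cross-validation, cuts are learned on the training folds
only and applied to the test fold, avoiding information leakage; a global
mode exists for sensitivity analysis. One caution on precision: when the two
classes are widely separated (say six standard deviations), most samples
contain a clean gap with a *single* candidate threshold -- the midpoint of
the two inner extreme order statistics -- whose location fluctuates with
standard deviation around 0.3 at $n = 500$. The discretizer reliably finds
*one* boundary, but its exact placement inside a wide margin is
ill-determined by the data itself, and mixtures that overlap more actually
pin the boundary more precisely.

Very wide discrete panels (e.g. genotype tables) can be screened with
`chi2_rank()`: the raw Pearson statistic of each predictor-by-outcome table,
no continuity correction, used purely for ranking (no p-value thresholding).

## Evaluation protocol

`run_cross_validation()` implements stratified $k$-fold cross-validation
(default $k = 20$): folds are dealt round-robin within each outcome class,
so per-fold class counts are within one of perfect stratification. Per fold,
the tree is fitted once and each decision-path method fits one model per
test individual, so every individual is predicted exactly once per method.
If a cohort's smaller class has fewer members than $k$, $k$ is capped there
(a fold must not lose a class). Reported metrics: pooled and per-fold
Mann--Whitney AUC (with an across-fold $t$ interval, labelled as such --
other interval constructions exist), the Brier score as $1-\mathrm{BS}$, and
the Brier skill score against the prevalence forecaster, which scores
exactly 0 by construction. `paired_t_test()` compares methods across
cohorts; with seven cohorts the test has 6 degrees of freedom, and no
multiplicity correction is applied by default. `disagreement_proportion()`
reports how often a personalized model differs from the tree, both as
thresholded predictions (0.5) and as conjunct *sets*, because a path can
differ while the prediction agrees.

## Synthetic cohorts

Because real clinical registries cannot ship with a package, every stage is
exercised on seeded generators. `gen_path_process()` plants a conditional
table $P(T\,|\,\text{signal pattern})$ behind a few binary signal variables
among independent discrete noise (domains 2--4, echoing discretized clinical
measurements), optionally with MCAR missingness, and reports the ground
truth: signal set, each row's true outcome probability, and the Bayes-optimal
AUC computed by brute-force pair counting over the generated rows (for the
default single signal with $P(T{=}1\,|\,V{=}1) = 0.9$,
$P(T{=}1\,|\,V{=}0) = 0.1$ and balanced $V$, that is
$0.81 + \tfrac12\cdot0.18 = 0.90$ -- concordant pairs plus half credit for
the ties a two-valued score necessarily produces).
`make_benchmark_suite()` generates seven cohorts whose predictor counts,
sample sizes and prevalences (4.5%--61%) mirror the spread of real clinical
and genomic prediction problems, at a default 1/10 sample-size scale so the
full suite cross-validates in seconds; signal enters through a calibrated
logistic model on three discrete variables plus one continuous variable, the
latter exercising per-fold discretization end to end.

What the generators do *not* emulate: correlated predictors, linkage
structure between markers, informative missingness, measurement drift, or
label noise. Passing tests on these cohorts demonstrates that the machinery
recovers planted structure under the stated conditions -- not that any
particular clinical performance level will be attained on real data.

## Numerical and design choices

* Candidate ties break toward the variable earliest in schema order;
  pruning ties toward the shortest prefix; tree pruning ties toward
  collapse. All deterministic.
* AUC tie credit is exact ½ per tied pair (midranks); inside the C++ LOOCV
  criterion, scores within $10^{-12}$ are treated as tied.
* `pess` defaults to 1 ($\alpha_{jk} = 1/2$, $\alpha_j = 1$ on binary
  outcomes); all smoothing, split scoring and leaf estimation share it.
* Rows with a missing outcome are dropped at construction (counted); they
  can contribute to no score.
* Classification threshold 0.5 wherever a hard label is needed.
* Fold assignment, generators and the CLI take explicit integer seeds; the
  caller's RNG state is always restored.

Problem sizes used by the shipped tests: oracle equivalence on 200 random
cohorts of at most 4 predictors and 12 rows against a brute-force greedy
reimplementation, for all three criteria; the exact Dirichlet--multinomial
check on all 784 two-sample binary tables with up to 6 individuals per
sample; signal recovery on 100 seeded cohorts of $n = 2000$ with 20 noise
variables; and the seven-cohort benchmark suite at 1/10 scale across 10
seeds, comparing the Bayesian path learner with the population tree on
pooled AUC and Brier skill.

## Limitations

* Only discrete (or discretized) predictors and discrete outcomes; the AUC
  criterion is binary-only. No disjunctions, no best-first search, no model
  averaging -- one conjunction per patient, by design.
* Cross-depth comparison of recorded path scores is still a heuristic, even
  on the full-cohort scale; the argmax rule inherits greedy growth's
  shortsightedness.
* The population tree is a faithful *style* of comparator, not a
  reproduction of any specific CART configuration, so numeric results
  against other tree implementations will differ.
* At very small subgroup sizes the LOOCV AUC criterion is noisy (a
  two-member subgroup's predictions are anti-correlated with the held-out
  labels by construction), which is visible as the AUC-driven learner's
  weaker benchmark performance.
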