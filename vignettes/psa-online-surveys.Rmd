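---
title: "Propensity score adjustment for volunteer online samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propensity score adjustment for volunteer online samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psaml)
```

## The problem

Volunteer online panels are self-selected from the subpopulation with
internet access. Two things go wrong at once: coverage (people without
access can never appear) and self-selection (among those with access,
the propensity to participate varies with characteristics that may also
drive the survey outcome). Unweighted estimates from such samples can
carry bias that does not shrink with sample size.

Propensity Score Adjustment (PSA) attacks both with one extra
ingredient: a probability *reference sample* from the full population
that measured the same covariates $\mathbf{x}$ (but not the outcome
$y$, which only the volunteer sample has). Stack the two samples and
define the membership indicator

$$ z_i = \begin{cases} 1 & i \in s_v \text{ (volunteer)} \\
                       0 & i \in s_r \text{ (reference)} \end{cases} $$

for the $n = n_{vs} + n_{rs}$ stacked units. The participation
propensity $\pi(\mathbf{x}_i) = P(z_i = 1 \mid \mathbf{x}_i)$ is
estimated from this stacked sample and converted into weights for the
volunteer units.

## Weighting schemes

Two schemes are implemented, selected by `weighting =` in
`run_scenario()` / `psa_weight()`:

* **Propensity classes (Horvitz–Thompson type)**,
  `ht_class_weights()`: the combined sample is sorted by $\hat\pi$ and
  cut into $C$ classes at the quantiles of the combined propensity
  distribution ($C = 5$ is the standard recommendation and our
  default). Within class $c$ the adjustment factor is the ratio of
  weight shares,
  $$ f_c = \frac{\sum_{k \in s_{rc}} d_k^r / \sum_{k \in s_r} d_k^r}
                {\sum_{j \in s_{vc}} d_j^v / \sum_{j \in s_v} d_j^v}, $$
  and each volunteer unit in the class gets $w_j = f_c\, d_j^v$. The
  construction telescopes: the total volunteer weight mass is conserved
  exactly, which the tests verify to $10^{-10}$.
* **Inverse odds (Hajek type)**, `hajek_weights()`:
  $w_j = (1 - \hat\pi_j)/\hat\pi_j$. These weights target the
  population the reference sample represents. They are undefined at
  $\hat\pi \in \{0, 1\}$, values that tree-based estimators produce
  readily, so raw propensities pass through the fixed transformation
  $(1000x + 0.5)/1001$ (`clip_propensities()`) first — it maps
  $[0,1]$ into $(0,1)$, leaves $0.5$ fixed and preserves order.

Estimates use the normalised ratio form $\sum w_j y_j / \sum w_j$ for
both schemes. The paper-of-record for the Hajek weights leaves the
scale of the raw weighted total ambiguous; normalising removes that
ambiguity, keeps every estimate inside $[\min y, \max y]$, and makes
the two schemes coincide exactly when $\hat\pi$ is constant (an
invariant the tests assert).

## Propensity estimators

`fit_propensity()` dispatches on a `propensity_spec()`. Logistic
regression is the classical choice; the five machine-learning
estimators exist because the logistic model's linear log-odds
assumption is exactly what fails in realistic selection mechanisms.
All six consume the same design matrix (numeric covariates as-is,
categoricals one-hot in sorted level order), except naive Bayes (see
below). Base design weights never enter the fits; they matter only at
the weighting stage.

| algorithm | estimate of $\hat\pi(\mathbf{x}_i)$ | tuning grid |
|---|---|---|
| `logistic` | $1/(1 + e^{-\gamma^T \mathbf{x}_i})$, ML fit | — |
| `tree` | volunteer fraction of the terminal node | impurity (entropy/gini), prune confidence {0.1, 0.25, 0.5}, min node {0.5, 1, 5}% |
| `random_forest` | fraction of trees whose terminal node is majority-volunteer | 500 trees, mtry {1, 2, 4} or {√p, p/2, p} |
| `knn` | volunteer fraction among the k nearest other units | k {3, 5, 7, 9, 11, 13} |
| `naive_bayes` | Bayes formula with class-conditional independence | Laplace λ {0, 1, 2, 5, 10} |
| `gbm` | $1/(1 + e^{-w^T J(\mathbf{x}_i)})$, stagewise trees | depth {4, 6, 8}, learning rate {0.1, 0.01, 0.001} |

Numerical and design choices that were genuinely open:

* **Tree learner.** No recursive-partitioning learner is assumed
  installed, so the package carries its own: binary threshold splits on
  the encoded matrix, impurity `entropy` (standing in for C4.5/C5.0)
  or `gini` (CART), a minimum-node-size knob expressed as a fraction
  of $n$, and confidence-based pessimistic pruning using the exact
  Clopper–Pearson upper bound of the node error rate — smaller
  confidence inflates the bound more and prunes harder, the C4.5
  convention. C5.0's winnowing/rule-set/boosting-trials options are
  not reproduced; where both have been compared, C4.5-style and
  C5.0-style trees behave nearly identically for propensity work.
* **Random forest vote.** A tree votes 1 for a unit whose terminal
  node has volunteer fraction $\ge 0.5$; the propensity is the vote
  fraction over trees. Covariates are subsampled *per tree* (not per
  split), matching the vote-fraction formulation; trees are unpruned
  with minimum node size 1 on bootstrap resamples. Under unbalanced
  $n_{vs}/n_{rs}$ most leaves are majority-volunteer and raw
  propensities crowd toward 1 — this is a property of the estimator,
  not a bug, and is why clipping precedes Hajek weighting.
* **k-NN ties.** The distance definition scales numeric covariates to
  $[0,1]$ (min–max over the combined sample) and leaves one-hot
  dummies as-is, Euclidean metric. A unit is excluded from its own
  neighbourhood. Distance ties at the k-th neighbour are broken by
  lowest row index so exactly $k$ neighbours count; counting *all*
  units within the k-th distance would let the estimate's denominator
  disagree with its numerator under heavy ties. Consequence worth
  knowing: in tiny clustered configurations the "obvious" 0/1 answers
  can be unattainable — with 3 volunteers at one location and $k = 3$,
  excluding self leaves only 2 same-cluster neighbours, so the third
  vote always crosses clusters and the exact value is $2/3$, which the
  brute-force oracle in the tests confirms.
* **Naive Bayes input.** Eq.-level naive Bayes cross-tabulates the
  *original* categorical covariates, so this estimator reads the raw
  stacked columns rather than the one-hot matrix: factors get add-λ
  (Laplace) smoothing over their observed level set, numeric
  covariates get per-class Gaussian conditionals with the standard
  deviation floored at $10^{-9}$ (a constant-within-class covariate
  stays usable). Feeding it one-hot dummies instead would silently
  model binary indicators as Gaussians.
* **GBM.** Bernoulli deviance, depth-limited regression trees on the
  gradient residuals $z_i - p_i$, one-step Newton leaf values
  $\sum r / \sum p(1-p)$ capped at $\pm 4$, shrunk by the learning
  rate. The reference description fits each tree on "a small sample"
  of the data without giving a number: the default here is 100 trees
  with 50% row subsampling per iteration. With subsampling the
  no-information fit drifts slightly off the base rate (an unbalanced
  bag gives a nonzero Newton step, as in reference GBM
  implementations); with `bag_fraction = 1` it returns
  $n_{vs}/n$ exactly and its training deviance is non-increasing,
  which the tests assert.

## The simulated world

`generate_population()` produces the fictitious voter population used
by the Monte-Carlo engine: $N = 50{,}000$ by default, age
$= 82x + 18$ with $x \sim \beta(2,3)$ (an age pyramid close to
Spain's), nationality, education and internet access conditional on
the three age strata (under 35 / 35–65 / over 65), gender 50/50
independent of everything. Internet access ranges from 90% (young
natives) to 0% (non-natives over 65), so roughly 64% of the population
— about 31,900 people — is reachable by an online survey.

Three vote indicators encode three selection mechanisms:

* **Party 1 — MCAR.** 20% of women, no men. Gender is independent of
  internet access, so an internet-only sample is selection-unbiased
  for it.
* **Party 2 — MAR.** 0/40/60% by age stratum. Age drives access, so
  the volunteer sample under-represents older voters, but the bias is
  fully explained by observed covariates.
* **Party 3 — NMAR.** 10% without access; 60/40/20% by stratum with
  access. The outcome depends on the selection variable itself:
  covariate-based reweighting can shrink but not remove this bias.
  Analytically, the internet-domain truth exceeds the population truth
  by $+0.114$, which is what the unadjusted estimator's bias converges
  to.

The vote indicators are drawn independently per person — the three
proportions are estimated separately and nothing constrains a person
to one party. Truths are the *empirical* fractions of the realised
population (`true_proportion()`), so bias and MSE are exact for the
finite population actually simulated, not for the generator's
expectations.

Convenience samples are drawn from the internet subpopulation by one
of three schemes (`draw_convenience()`): uniform SRSWOR, or unequal
self-selection with $\pi_i = 1/(1 + e^{-1 + 0.05\,\mathrm{age}_i})$
(log-linear in age, decreasing) or
$\pi_i = 1/(1 + e^{1 - \sin(\mathrm{age}_i/20)})$ (non-monotone).
These formulas give per-unit probabilities but the study design fixes
$n_{vs}$; the fixed-size mechanism is not specified in the source
material, so the package uses sequential without-replacement draws
with probability proportional to $\pi$ among the remaining units
(base R's weighted sampling) — one defensible realisation, flagged
here because other fixed-size $\pi$ps designs exist. The reference
sample is SRSWOR from the full population with design weights $N/n_{rs}$;
volunteer base weights are 1 (their true design is unknown — that is
the problem PSA addresses).

What a green simulation test does **not** establish: the generator has
clean conditional independencies and four strong covariates; real
volunteer panels have weaker, noisier covariates, measurement error,
and selection on unobservables beyond internet access. The real-data
behaviour of these estimators must be judged on real data (the
`psa_weight()` generic mode exists for exactly that).

## The Monte-Carlo engine

`run_scenario()` generates one population per study (not one per
replication — the finite-population truth stays fixed, as in the
reference design) and then, per replication, redraws both samples,
refits every configured estimator, reweights and re-estimates. Per
party $k$ and estimator,

$$ \mathrm{Bias}_k = \frac{\sum_{m=1}^{M} \hat p_m^k}{M} - p^k, \qquad
   \mathrm{MSE}_k = \frac{\sum_m (\hat p_m^k - \bar{\hat p}^k)^2}{M - 1}
   + \mathrm{Bias}_k^2, $$

with $M = 500$ replications by default (desk-scale runs override
`reps`). The identity MSE = sample variance + squared bias is asserted
to $10^{-12}$ in the tests. Estimator seeds are derived per
(replication, estimator) from the master seed via named substreams, so
all estimators see identical samples — a paired design that removes
between-sample noise from algorithm comparisons, chosen here because
the source design is silent on pairing.

`tune_cv()` implements the hyperparameter search: 10-times repeated
10-fold cross-validation scored by Bernoulli log-loss of out-of-fold
propensities (clipped to $(10^{-15}, 1 - 10^{-15})$), ties broken by
grid order. Log-loss, not accuracy: the goal of these classifiers is a
well-calibrated participation probability, not a good class label.

## Degenerate inputs and edge policies

* A combined sample with only one membership class refuses to fit.
* A propensity class lacking one sample type merges with its
  neighbour toward the centre of the class range (warned); the
  weight-mass conservation survives merging.
* All-identical propensities collapse to a single class (warned) and
  reproduce the unadjusted estimate exactly under both schemes.
* Logistic separation warns and returns the capped-iteration fit;
  clipping then makes the weights finite.
* `srswor(table, n = nrow(table))` returns the whole table with unit
  weights; `n` larger than the table errors.

## Known limitations

* Only single-stage design weights for the reference sample; no
  stratified/clustered designs.
* No analytic variance estimation for the weighted estimators — the
  Monte-Carlo engine is the uncertainty tool.
* No post-PSA calibration/raking, Super Learner, neural networks or
  matching estimators.
* The in-package tree is a faithful but deliberately compact learner;
  it does not reproduce every C5.0 refinement.
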