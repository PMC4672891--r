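---
title: "Comprehensible risk models from comorbidity features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comprehensible risk models from comorbidity features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electronic medical records reduce a hospital stay to a wide, sparse table:
a few numeric covariates (age, length of stay, counts, charges) and
hundreds of 0/1 indicators for the presence of diagnosis codes. Predicting
a binary endpoint such as 30-day readmission from such a table is easy to
do acceptably with a large penalized regression — and hard to do
*comprehensibly*. A model with a hundred coefficients, however accurate,
is not something a clinician will read. `comologit` trades a sliver of
regularization freedom for models built from terms a domain expert can
parse at sight, and measures the cost of that trade explicitly.

Model complexity here always means the number of nonzero regression
coefficients, excluding the intercept — the working proxy for
comprehensibility throughout the package.

## The model

For binary diagnosis indicators $d_j \in \{0,1\}$ and numeric covariates,
the fitted object is a logistic regression over four kinds of terms:

$$
\mathrm{logit}\,P(y=1\mid x) \;=\; \beta_0
 + \sum_j \beta_j d_j
 + \tfrac12\sum_{j \ne k} \theta_{jk}\, d_j d_k
 + \sum_{j<k} \gamma_{jk}\, d_j d_k^c
 + \sum_{j<k} \delta_{jk}\, d_j^c d_k ,
$$

where $d^c = 1 - d$. The two complement ("comorbidity") terms are the
distinctive ingredient: $d_j d_k^c$ reads "diagnosis $j$ present *and*
diagnosis $k$ absent". A *switching* pattern — risk elevated when exactly
one of two diagnoses is present, but not when both or neither are — has a
natural two-coefficient representation in this basis
($\gamma = \delta = c$), while in the plain product basis it needs three
mutually cancelling coefficients ($\beta_j = \beta_k = c$,
$\theta_{jk} = -2c$). Sparse selection therefore prefers the complement
representation exactly when the data carry such a pattern, which is what
makes the resulting models both smaller and more readable.

## The three-stage pipeline

**Stage 1 — hierarchical interaction screening.** Fitting all
$\binom{p}{2}$ interactions at once is neither tractable nor desirable.
The screen solves an overlapped ("latent") group-lasso logistic
regression: each main effect is its own singleton group, and every
candidate pair $(j,k)$ owns a three-vector latent group holding copies of
both main-effect columns plus the product column. Because an interaction
can only enter through a group that carries its main effects, strong
hierarchy holds by construction. The penalty weight of a pair group is
$\sqrt{3}$ (the square root of the group size); singleton main groups have
weight 1, which keeps a main effect cheaper through its own group than
through any pair group.

The path starts at $\lambda_{\max}$, computed from the null-model
gradient, and walks 50 log-spaced values down to
$0.01\,\lambda_{\max}$, stopping at the first $\lambda$ with at least
NDI (number of discovered interactions, a user choice) active pair
groups. Interactions are reported in order of path entry, ties broken by
larger group norm and then lexicographic label. If the floor is reached
first, all discovered pairs are returned and the result is flagged
truncated. With `ndi = 0` the path is walked in full and the
cross-validated $\lambda$ supplies the main effects.

The solver is FISTA with backtracking line search and adaptive restart,
run on an exact active set: the restricted problem is solved to a
relative-objective tolerance of $10^{-8}$ (capped at 10,000 iterations;
non-convergence is logged, not fatal), then a full Karush–Kuhn–Tucker
sweep over all inactive groups adds any violator and the solve repeats
until no violations remain. This yields the full-space optimum — it is an
exact device, not a screening heuristic — and was adopted because a
full-space FISTA iteration on $\binom{53}{2}$ latent groups wastes almost
all of its work on groups that never activate near the top of the path.

Inside the solver, every column is centered and numeric features are
additionally scaled to unit variance; binary indicators are not scaled,
so their coefficients remain per-diagnosis log-odds (centering a 0/1
column shifts only the intercept). Product candidates are built from the
*centered* columns and then scaled to unit standard deviation. Both
choices matter for discovery quality: a product of raw low-prevalence
indicators has a gradient bounded by its prevalence (pairs would compete
on prevalence rather than on correlation with the residual), and a
product of uncentered columns correlates with its own main effects, so
that early in the path — where main effects are still heavily shrunk —
pair groups would activate merely to absorb main-effect residual.
Centered, unit-variance products are first-order interaction contrasts,
and pair groups then compete on genuine interaction signal. Coefficients
are reported back on the original scale (de-centering propagates product
terms into main effects and intercept where necessary).

**Stage 2 — complement expansion.** Each discovered pair of *binary*
features contributes its product term plus the two complement terms; pairs
with a numeric member contribute the product only, since the complement of
a numeric feature is undefined (each skip is logged). The both-absent
combination $d_j^c d_k^c$ is intentionally not generated: it is the
intercept region. The expanded design is deliberately collinear
($d_j = d_j d_k + d_j d_k^c$); pruning is the next stage's job, and strong
hierarchy is deliberately given up from here on.

**Stage 3 — sparse re-selection.** A lasso-penalized logistic regression
over the expanded terms, solved by cyclic coordinate descent on the
quadratic-majorized working response with warm starts along a 100-point
log-spaced grid down to $10^{-4}\lambda_{\max}$. Solutions are accepted
only when the exact KKT conditions of the true objective hold to
$10^{-7}$ (the IRLS weights are floored at $10^{-5}$, as in standard
practice, to keep working responses bounded on near-separable complement
columns). Penalization is on the same scale logic as stage 1: numeric
columns standardized internally, 0/1 columns raw.

The penalty is tuned by 5-fold stratified cross-validation on held-out
AUC — not deviance, because the selection rules are defined on AUC. Two
models are kept: **OPT**, the $\lambda$ maximizing mean out-of-fold AUC
(ties resolved toward the larger, sparser $\lambda$), and **1SE**, the
largest $\lambda$ whose mean AUC is within one standard error
(fold standard deviation / $\sqrt{5}$) of the maximum. The same AUC
criterion is applied uniformly to the stage-1 and stage-3 tuning; the
class imbalance is left unweighted.

## Evaluation protocol

`repeated_holdout()` repeats: split the data 2/3 train / 1/3 test
(stratified by outcome, so the rare class is present in every test set);
run stages 1–3 on the training part; score three arms on the test part —
the *baseline* (the stage-1 group-lasso model at its own cross-validated
$\lambda$, carrying main effects and products but no complements), OPT
and 1SE. Per repeat it records held-out AUC and complexity; summaries are
the mean and the 2.5/97.5 percentile interval across repeats (the
percentile reading of a 95% interval over repeat-level values). Repeats
that fail are skipped with a warning; more than 10% failures aborts.

Because the baseline differs from OPT only in the absence of complement
features (and in being the group-lasso rather than the re-selected fit),
the protocol isolates what the complement expansion buys. Selection
stability is summarized by `frequency_table()`: for each coefficient
sign, the percentage of repeats in which each term was selected under OPT
and under 1SE, ranked by the OPT percentage — the classic ranked
comorbidity-table layout.

`interaction_response_surface()` fits two unpenalized logistic models on
two numeric covariates, with and without their product term, over a grid
spanning the observed ranges — the standard demonstration that a negative
interaction (e.g. between log length-of-stay and chronic-condition count)
bends the risk surface downward where both covariates are high, a shape
the additive model cannot express.

## The synthetic EMR generator

No patient-level discharge data ships with the package; every claim the
test suite makes is exercised on synthetic data from `simulate_emr()`,
designed to emulate the structure of a pediatric discharge table:

* 50 binary indicators by default, with a deterministic geometric
  prevalence ladder from 0.15 down to 0.005 — diagnosis indicator sets
  are built from the most frequent codes, so prevalences fall off
  quickly and the ladder makes that explicit and reproducible;
* numeric covariates: lognormal length of stay, its log1p companion
  (mirroring the practice of adding log-transformed copies), and a
  Poisson(1.5) chronic-condition count;
* planted effects covering every term kind, including a switching pair
  (complements at +2/+2 with zero product effect) and a negative
  numeric-by-numeric interaction;
* a Bernoulli outcome under the logistic link. The generating equations
  are often written in linear form with an error term $\varepsilon$; for
  a binary endpoint the Bernoulli-logistic reading is the only internally
  consistent one, and it is what the generator implements;
* the intercept, unless given, is calibrated by root-finding on the
  realized covariates so that the event rate is 0.175 — the class
  balance of the motivating readmission problem (10,675 of 61,111
  records positive);
* optionally, a single latent factor induces tetrachoric correlation
  between indicators for stress tests; indicators are independent by
  default, since co-occurrence strength is a nuisance dimension rather
  than a modelled claim.

What the generator does *not* emulate: real ICD code semantics,
visit/longitudinal structure, informative missingness (the reader rejects
missing values outright), or the heavy-tailed charge variables. Passing
tests on this generator therefore demonstrate correctness of the
machinery and the in-kind behavior of the method (switching patterns are
found, complements beat product-only models where they should, sparser
rules give smaller models) — not clinical performance on any real
population.

## Numerical choices and degenerate inputs

* $\lambda$ grids: stage 1 uses 50 points to a floor of
  $0.01\lambda_{\max}$ (discovery happens near the top of the path);
  stage 3 uses 100 points to $10^{-4}\lambda_{\max}$ (the refit must be
  able to approach the unpenalized model). Both are exposed as arguments.
* Ties in the OPT rule go to the largest $\lambda$; ties in discovery
  order go to the larger group norm, then the lexicographic label.
  Product descriptors store their member names in lexicographic order,
  making symmetry canonical.
* Columns with zero variance get scale 1 (no division by zero) and can
  never activate; a product of two indicators that never co-occur is an
  all-zero column and is inert by the same argument.
* Datasets must contain both outcome classes; stratified folds that
  still end up single-class (tiny n) raise an error advising fewer
  folds. Separable surface fits raise an error suggesting a ridge
  fallback rather than returning diverged coefficients.
* All randomness (generation, splits, fold assignment) flows from
  explicit integer seeds through a private RNG scope that restores the
  caller's stream; fixed seeds give bit-identical datasets and identical
  evaluation reports.

## Problem sizes used by the packaged checks

The packaged test suite and the acceptance script run at desk scale,
chosen as the smallest sizes at which each property is comfortably
demonstrated: solver-against-oracle checks on instances of up to 200
rows; interaction recovery at n = 5,000 over 20 seeds; the switching
comparison at n = 10,000 with 50 hold-out repeats; the complexity-ordering
and coefficient-recovery checks on the full paper-like scenario
(n = 20,000, 53 features). The 1000-repeat protocol of the motivating
study is available by setting `repeats = 1000`.

## Known limitations

* Only pairwise interactions are considered; re-running stages 1–2 on an
  expanded basis would be the route to higher-order logic terms and is
  not implemented.
* The screen's exact active-set strategy is quadratic in the number of
  features per KKT sweep; hundreds of features are comfortable,
  thousands would call for the screening heuristics deliberately left
  out.
* The baseline arm is a penalized model evaluated at a cross-validated
  $\lambda$ on a path truncated at the NDI stop; with very small NDI its
  fits are strongly shrunk, which should be kept in mind when reading
  baseline AUC in absolute terms.
* Complement features are defined for binary pairs only; no
  discretization of numeric features is attempted.
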