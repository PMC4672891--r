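# comologit

Comprehensible sparse logistic risk models with comorbidity features.

## What problem this solves

Risk models built from electronic medical records — predicting, say,
hospital readmission within 30 days of discharge — work on wide tables
of 0/1 diagnosis indicators plus a few numeric covariates (age, length
of stay, chronic-condition counts, charges). Penalized logistic
regression handles the width, but the resulting models routinely carry
dozens to hundreds of coefficients, which defeats the point of a model a
clinician is supposed to read. `comologit` is for analysts who want a
*small* model whose terms read like clinical statements — including
comorbidity statements such as "neutropenia present **and** leukemia
absent" — and who want the accuracy cost of that compactness measured
rather than asserted.

## The model and method

The fitted object is a sparse logistic regression over four kinds of
terms on binary indicators `d_j` (with complement `d^c = 1 - d`) and
numeric covariates:

    logit P(y = 1 | x) = b0 + sum_j beta_j d_j
                            + sum_{j<k} theta_jk d_j d_k
                            + sum_{j<k} gamma_jk d_j d_k^c
                            + sum_{j<k} delta_jk d_j^c d_k

The complement terms can express a *switching* pattern — risk elevated
when exactly one of two diagnoses is present — with two coefficients,
where the plain product basis needs three mutually cancelling ones.
Three stages produce the fit:

1. **Screen** (`discover_interactions`): an overlapped group-lasso
   logistic path discovers a user-set number of pairwise interactions
   (NDI) under strong hierarchy — an interaction enters only together
   with its main effects.
2. **Expand** (`expand_logical`): each discovered binary pair adds its
   two complement features alongside the product; numeric pairs stay
   product-only.
3. **Re-select** (`fit_lasso_logistic` / `cv_tune`): a lasso logistic
   regression over the expanded terms, tuned by 5-fold cross-validated
   AUC under two rules — **OPT** (AUC-optimal penalty) and **1SE**
   (largest penalty within one standard error of the optimum, i.e. the
   sparser model).

`repeated_holdout()` evaluates the pipeline by repeated stratified
2/3 – 1/3 splits, reporting held-out AUC and model complexity (number of
nonzero coefficients) for the OPT and 1SE models against the
interaction-only group-lasso baseline, and `frequency_table()` ranks
terms by how often they were selected across repeats — a stability view
of which comorbidities matter. A synthetic EMR generator
(`simulate_emr`) with planted main, product and switching effects makes
everything testable without access to restricted discharge data.

## Worked example

```r
library(comologit)

## a synthetic EMR-like table: 10,000 records, 12 diagnosis indicators,
## length of stay (+ log), chronic count; risk is raised when exactly one
## of dx01/dx02 is present (complement effects +2/+2, no product effect)
cfg <- emr_config(
  n_samples = 10000, n_binary = 12,
  prevalences = c(0.2, 0.2, rep(0.1, 10)),
  effects = list(
    effect(left_only_term("dx01", "dx02"), 2.0),
    effect(right_only_term("dx01", "dx02"), 2.0),
    effect(main_term("dx03"), 0.7),
    effect(main_term("los_log"), 0.4)),
  seed = 1)
ds <- simulate_emr(cfg)

fit <- comologit(ds, ndi = 2, seed = 7)
print(fit)
coef(fit, rule = "1se")
```

The fit prints the discovered interactions and the three models
(output from this exact call):

```
Comprehensible comorbidity risk model
Call: comologit(data = ds, ndi = 2, seed = 7)

Interactions discovered (NDI = 2): 2
Expanded terms: 10
  baseline  complexity   6  (lambda 0.0087436)
  opt       complexity   4  (lambda 0.0012038)
  1se       complexity   4  (lambda 0.0070505)
```

and the 1SE coefficients are the readable story: the two complement
terms carry the switching pattern (true value +2 each, shrunk by the
penalty), the two genuine main effects come along, and the product
"dx01 AND dx02" is correctly judged unnecessary:

```
> round(coef(fit, rule = "1se"), 4)
          (Intercept)                  dx03               los_log
              -2.3897                0.1569                0.1676
dx01 = 1 AND dx02 = 0 dx01 = 0 AND dx02 = 1
               1.4046                1.4329
```

Evaluation compares the arms:

```r
ev <- repeated_holdout(ds, ndi = 2, repeats = 50, seed = 11)
print(ev)
frequency_table(ev, "positive")
```

which reports mean held-out AUC with 2.5/97.5 percentile intervals per
arm, mean complexity per arm (1SE smallest), and the ranked
selection-frequency table in which the two complement features sit at
the top.

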