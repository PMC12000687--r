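---
title: "Building short questionnaire forms by Lasso selection and re-weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building short questionnaire forms by Lasso selection and re-weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facsimile)
library(dplyr)
```

## The problem

Long self-report questionnaires burden participants, degrade data quality and
cost money. Given a validated full-length measure, we often do not need every
item: a well-chosen, re-weighted subset can predict the scores the full
measure would have produced — total sum scores, subscale sums, or factor
scores from an exploratory factor analysis (EFA) — with high accuracy.

`facsimile` implements the FACSIMILE approach (factor score item reduction
with Lasso estimation). The model is an ordinary linear one: an observed
score $y$ is approximated as a weighted sum of item responses,

$$\hat{y} = w_1 x_1 + w_2 x_2 + \dots + w_p x_p + \epsilon .$$

With every item present this prediction is exact (unit weights for a sum
score), so the interesting question is how little we lose as items are
dropped. The Lasso (L1-penalized regression) answers it by driving
uninformative weights exactly to zero at a chosen regularization strength
$\alpha$.

## The two-step fit

For multidimensional targets (several subscales or factors), a single shared
$\alpha$ is rarely best: an easy dimension needs few items, a hard one many.
A multi-task Lasso with one shared penalty is therefore not used. Instead:

1. **Select per dimension.** For each target dimension, fit a Lasso
   regression of that dimension on all items at its own strength $\alpha_d$
   (`select_items_lasso()`). Items are z-scored inside this step (training
   mean, population SD) so $\alpha$ is insensitive to item coding; the
   objective is $(1/2n)\,\mathrm{RSS} + \alpha \lVert w \rVert_1$ with an
   unpenalized intercept.
2. **Pool and refit.** Take the union of items selected for any dimension
   (`union_included()`) and refit each dimension on the pooled items by
   ordinary least squares on the raw responses (`refit_union()`). Every
   dimension then benefits from any item the others needed; for a
   unidimensional target this step is redundant but harmless. Because the
   refit is an OLS on a superset of each dimension's selected items, its
   training $R^2$ can never fall below the step-1 value — a property the test
   suite checks on random instances.

`fit_facsimile()` runs both steps for a fixed $\alpha$ vector and returns an
`item_model`: the included items, an included-items × dimensions weight
matrix, and per-dimension intercepts. Excluded items have weight zero by
construction, so predictions ignore any extra columns. The intercept is not
part of the weighted-sum display above, but raw items are not centred while
factor scores are; estimating it in both steps keeps the method
scale-agnostic, and it comes out zero in the full-item sum-score case.

## Searching the brevity/accuracy frontier

There is no "correct" $\alpha$ — only a trade-off. `run_search()` repeats
the two-step fit for random strengths, each dimension drawing independently
from $\mathrm{Beta}(1,3) \times \text{scale}$, and scores every candidate on
a held-out validation set. Beta(1,3) concentrates draws at small strengths,
where most of the item-count action usually is. Each candidate is summarized
by its worst-dimension validation $R^2$ and by the selection score

$$\text{score} = \min_d(R^2_d) \cdot \left(1 - \frac{n_\text{included}}{n_\text{total}}\right),$$

which rewards accuracy on the *worst* dimension (a mean would hide a bad
subscale) and discounts longer forms. `best_model()` maximizes this score,
breaking ties in favour of fewer items and then the earlier iteration (the
tie-break is this package's choice; any rule consistent with the score would
do). `frontier_curve()` and `autoplot()` expose the full trade-off so users
can pick by eye instead.

Data are split once into training / validation / test partitions
(`split_data()`). Holdout sizes are the *ceiling* of their proportions and
training takes the remainder: 1622 participants at (0.6, 0.2, 0.2) give
972/325/325, the partition sizes this rule is designed to reproduce. The
final, chosen model is evaluated once on the test partition
(`evaluate_model()`).

### Choosing the scale of the draws

The useful range of $\alpha$ depends on the measure: its length, its item
coding and — critically — its internal consistency. The default scale of 8
suits a measure of roughly 22 items with moderate inter-item correlations.
`alpha_upper_bound()` computes, per dimension, the exact smallest strength
at which *no* item survives ($\max_j |z_j^\top (y - \bar y)|/n$); a scale
near that bound makes the random draws span the entire path.

Highly internally consistent scales compress the path's small-model region
into a narrow band near the upper bound, which Beta(1,3) samples rarely. For
unidimensional targets this costs nothing: the selected set is a
deterministic, stepwise function of $\alpha$ (one candidate per achievable
item count — the randomized search is redundant there), so `fit_k_items()`
simply bisects the strength until exactly `k` items survive. For several
dimensions it bisects a common multiplier of the per-dimension upper bounds,
a one-parameter path through the $\alpha$ space. Use it whenever the goal is
"the k-item version of this measure" rather than an open-ended frontier.

## Prediction targets

Three target kinds are supported, all per participant:

* `sum_scores()` — the row sum over all items.
* `subscale_scores()` — row sums over a disjoint, exhaustive item→subscale
  assignment.
* `factor_scores()` on a `fit_efa()` object — EFA scores. Extraction is by
  maximum likelihood on the item Pearson correlation matrix
  (`stats::factanal`), followed by an oblique oblimin (quartimin) rotation;
  the rotation is computed by a gradient-projection algorithm implemented in
  this package with a deterministic identity start, and the solution is put
  in a canonical form (dominant loadings positive, factors ordered by
  explained sum of squares). Factor scores use the regression (Thurstone)
  method, $F = Z R^{-1} \Lambda \Phi$ — the de-facto default of common
  factor-analysis toolchains. Neither the correlation type (Pearson rather
  than polychoric) nor the scoring method is dictated by the procedure
  itself; both are package decisions, recorded here.

`choose_n_factors()` operationalizes the scree judgment as the eigenvalue >
1 (Kaiser) rule and warns when nothing crosses the line; the full eigenvalue
sequence (`scree_eigenvalues()`, `plot_scree()`) is always available so a
human can overrule via the explicit `n_factors` argument.

Missing responses are rejected with an error by default; per-item mean
imputation is available behind an explicit flag (`na_impute = TRUE`). The
procedure itself never addresses missingness, so silence seemed worse than
refusal.

## The synthetic population

Because the method is demonstrated on data that cannot ship with the
package, `simulate_likert()` provides a fully known stand-in population. It
uses a linear common-factor model discretized through fixed thresholds —
exactly the structure the supported targets (sums, subscale sums, factor
scores) presuppose: latent factor scores are multivariate normal with a
specified factor correlation; each item's latent response is
`loadings %*% factors` plus a normal residual scaled to unit total variance
(so loadings read directly as correlations with the latent item); `k`
thresholds cut the latent value into `k + 1` integer categories.

The `"sticsa_like"` preset emulates a 22-item trait-anxiety questionnaire
with two correlated factors: 11 items per factor in simple structure,
primary loadings drawn once — under a fixed internal seed, so the preset is
a single stable population — uniformly in [0.80, 0.95], factor correlation
0.6, thresholds (−1, 0, 1) giving four roughly bell-shaped response
categories, and a default sample size of 1622. The `"unidim"` preset is a
10-item single-factor scale (loadings U(0.55, 0.85)) for unidimensional
examples.

What the generator does *not* emulate: careless or acquiescent responding,
missingness, and the strong floor effects of screening scales in unselected
populations. Passing tests on this population show the pipeline is correct
and behaves as designed on well-behaved, high-reliability data; they do not
certify performance on skewed screening measures, which are expected to be
harder. Note also that the preset's reliability (mean within-factor
inter-item correlation around 0.67) is at the high end of real
questionnaires, which shifts its regularization path upward: the smallest
strength that empties a total-sum model is about 12.5, beyond the default
scale-8 draw range, which is precisely the situation `alpha_upper_bound()`
and `fit_k_items()` exist for.

## Sample-size sensitivity

`sample_size_curve()` asks how training-set size affects achievable
accuracy. For each size (default 50–500) it draws subsamples with
replacement from the training pool (default 1000; reduce for quick looks),
reruns the randomized search on each subsample with a reduced iteration
budget (default 100), and records, per achieved item count, the best
worst-dimension $R^2$ on one *fixed* held-out partition. Using the fixed
partition — rather than re-splitting inside each subsample — keeps curves
comparable across sizes and avoids meaningless inner validation sets at
n = 50; since every candidate is recorded rather than selected, no inner
model selection is needed. The 95% band is a percentile (2.5/97.5) bootstrap
interval; the aggregation choice matters little at these subsample counts.

## Numerical choices

* The L1 solve is delegated to `glmnet` (single fixed penalty, convergence
  threshold `1e-16`), with closed forms for the single-predictor and
  $\alpha = 0$ cases; the test suite verifies agreement with an independent
  cyclic coordinate-descent implementation to $10^{-6}$ across an $\alpha$
  grid.
* Zero-variance items cannot be z-scored; they receive weight zero with a
  warning rather than an error, since floor-effect items are common in real
  data.
* Rank-deficient refits fall back to the minimum-norm least-squares solution
  (SVD pseudoinverse) with a warning.
* Random draws whose pooled item set is empty are dropped from the frontier
  with a message, not an error: at generous scales such draws are expected.
* All randomness is seed-controlled (`seed` arguments use a temporary RNG
  state and never disturb the caller's stream); identical inputs and seeds
  reproduce results exactly.

## Problem sizes used in the checks

The packaged checks run the full pipeline at moderate scale, chosen to make
sampling noise small relative to the margins being asserted: searches use
1000 iterations on 2500 synthetic respondents (split 1500/500/500) with
results taken as medians over three seeded replicates; the sensitivity
analysis uses 50 bootstrap subsamples per sample size with a 100-iteration
search budget; generator marginals are checked at $10^5$ respondents against
the normal-CDF oracle.

## Limitations

* Predictions from a reduced form are approximations; settings that need
  exact scores need the full measure.
* Scoring a short form requires the weight table (hence the spreadsheet
  export `export_weights()`), not just summing responses.
* The approach predicts scores; it offers no item-level measurement insight
  of the kind item-response-theory modelling provides, and predictions
  inherit whatever validity problems the full-length scores have.
* EFA here is exploratory Pearson-correlation EFA only; confirmatory models
  and polychoric-based extraction are out of scope (precomputed scores from
  any such model can still be supplied as a target matrix).
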