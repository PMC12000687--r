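# facsimile

Short forms of psychological questionnaires by Lasso item selection and
re-weighting.

## What it does

Validated self-report measures are often long, and long measures mean bored
participants, noisier data and higher cost. Given responses to a full-length
measure, `facsimile` derives a *short* form — a sparse, re-weighted subset of
items — whose predictions closely track the scores the full measure would
have produced: total sum scores, subscale sums, or factor scores from
exploratory factor analysis (EFA).

The model is a linear weighted sum of item responses,

```
ŷ = w₁x₁ + w₂x₂ + ⋯ + wₚxₚ + ε ,
```

fitted with the FACSIMILE two-step procedure:

1. **Select** — for each target dimension, an L1-penalized (Lasso)
   regression at strength α drives uninformative item weights exactly to
   zero; each dimension gets its own α, since easy dimensions need fewer
   items than hard ones.
2. **Re-weight** — the union of items selected for *any* dimension is
   refitted per dimension by unregularized least squares, so every dimension
   exploits every retained item.

A randomized search (α drawn from Beta(1,3) × scale, per dimension) maps the
brevity/accuracy frontier on a validation set; candidates are ranked by
`min(R²) × (1 − n_included/n_total)`, and the chosen model is evaluated once
on a test set. Weights export to a plain CSV so scores can be computed in a
spreadsheet, no code required.

A synthetic Likert-response generator with a known two-correlated-factor
structure (`likert_preset("sticsa_like")`: 22 items, 4-point scale, high
internal consistency) makes the whole pipeline runnable and testable without
any external dataset.

## Worked example

Derive a 10-item version of a 22-item two-subscale measure:

```r
library(facsimile)
library(dplyr)

spec <- likert_preset("sticsa_like")
dat  <- simulate_likert(spec, n = 2000, seed = 1)
idx  <- split_data(2000, c(0.6, 0.2, 0.2), seed = 1)

targets <- subscale_scores(
  dat$responses,
  setNames(rep(c("cognitive", "somatic"), each = 11), names(dat$responses))
)

frontier <- run_search(
  dat$responses[idx$train, ],      targets[idx$train, ],
  dat$responses[idx$validation, ], targets[idx$validation, ],
  n_iterations = 300, scale = 8, seed = 2
)
frontier_curve(frontier) |> head(6)
#> # A tibble: 6 × 4
#>   n_included    r2 iteration n_candidates
#>        <int> <dbl>     <int>        <int>
#> 1         10 0.955       217            1
#> 2         13 0.965        39            2
#> 3         14 0.955        48            4
#> 4         15 0.982        90           15
#> 5         16 0.986        20           18
#> 6         17 0.977       165            9
```

Each row is the best candidate at one length: with only 10 of 22 items the
worst-predicted subscale still reaches a validation R² of 0.955. The
brevity/accuracy score picks that 10-item model, and it holds up on the
held-out test partition:

```r
best <- best_model(frontier)
best$model[[1]]
#> <item_model> 10 of 22 items -> 2 dimensions (cognitive, somatic)
#>   training R2: cognitive = 0.975, somatic = 0.957

evaluate_model(best$model[[1]], dat$responses[idx$test, ], targets[idx$test, ])
#> # A tibble: 2 × 2
#>   dimension    r2
#>   <chr>     <dbl>
#> 1 cognitive 0.975
#> 2 somatic   0.954
```

So a form less than half the original length predicts both subscale sums
with test R² ≥ 0.95. When you want a *specific* length rather than a
frontier, `fit_k_items()` walks the deterministic regularization path
directly (here it lands on the same 10-item model). `export_weights()`
then writes the item weights and intercepts to CSV;
`predict_from_weights()` — or any spreadsheet — reproduces the model's
predictions from that file exactly.

Other entry points: `sum_scores()` / `subscale_scores()` / `fit_efa()` +
`factor_scores()` build the prediction targets; `sample_size_curve()`
bootstraps the accuracy-vs-training-size relationship; `autoplot()` methods
draw the frontier, observed-vs-predicted scatters, scree and sensitivity
plots; `inst/cli/facsimile.R` wraps the pipeline as a command line
(`simulate`, `targets`, `fit`, `evaluate`, `predict`, `export-weights`,
`sensitivity`).

See the vignette (`vignettes/short-form-methods.Rmd`) for the method's
assumptions, parameter meanings and design decisions.

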