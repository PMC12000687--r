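#' Lasso item selection for one target dimension
#'
#' Step 1 of the two-step reduction: an L1-regularized linear regression of a
#' single target dimension on all items drives uninformative item weights
#' exactly to zero. Items are z-scored internally (training mean and
#' population SD) so the regularization strength `alpha` has a scale-free
#' meaning across measures; the objective is
#' `(1/2n) * RSS + alpha * sum(|w|)` with an unpenalized intercept. At
#' `alpha = 0` the fit is ordinary least squares.
#'
#' @param data Participants x items training responses (data frame or matrix).
#' @param target Numeric vector (or single-column data frame) of training
#'   scores for one dimension.
#' @param alpha Non-negative regularization strength.
#' @param dimension Label for the dimension (used in reporting).
#' @return An object of class `lasso_selection`: `dimension`, `alpha`,
#'   `coefficients` (per item, on the z-scored item scale; zeros mark
#'   exclusion), `intercept`, `included_items`, `training_r2`.
#' @export
#' @examples
#' dat <- simulate_likert(likert_preset("unidim"), n = 200, seed = 1)
#' sel <- select_items_lasso(dat$responses, sum_scores(dat$responses)$total, alpha = 0.5)
#' sel$included_items
select_items_lasso <- function(data, target, alpha, dimension = "target") {
  x <- as_response_matrix(data)
  y <- as_target_matrix(target, n_rows = nrow(x), arg = "target")
  if (ncol(y) != 1L) {
    abort("`target` must be a single dimension; use `fit_facsimile()` for several.")
  }
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 2L) abort("At least 2 participants are required.")
  check_scalar_number(alpha, "alpha", min = 0)

  mu <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2, mu)^2)) # population SD, matching the 1/n objective
  zero_var <- sds <= 0
  if (any(zero_var)) {
    warn(sprintf(
      "Zero-variance items receive weight 0: %s.",
      paste(colnames(x)[zero_var], collapse = ", ")
    ))
  }
  active <- which(!zero_var)
  if (length(active) == 0L) {
    abort("All items have zero variance; nothing to select from.")
  }
  xs <- sweep(sweep(x[, active, drop = FALSE], 2, mu[active]), 2, sds[active], "/")

  beta_active <- fit_lasso(xs, y, alpha)
  beta <- stats::setNames(numeric(ncol(x)), colnames(x))
  beta[active] <- beta_active
  intercept <- mean(y) # columns are centred, so the intercept is the target mean
  fitted <- as.numeric(xs %*% beta_active) + intercept
  structure(
    list(
      dimension = dimension,
      alpha = alpha,
      coefficients = beta,
      intercept = intercept,
      included_items = colnames(x)[beta != 0],
      training_r2 = r_squared(y, fitted)
    ),
    class = "lasso_selection"
  )
}

# Solve min (1/2n)||y - b0 - X w||^2 + alpha ||w||_1 for z-scored X.
# glmnet carries the path algorithm; the single-predictor and alpha = 0 cases
# use their closed forms for exactness.
fit_lasso <- function(xs, y, alpha) {
  n <- nrow(xs)
  p <- ncol(xs)
  yc <- y - mean(y)
  if (alpha == 0) {
    fit <- lm.fit(cbind(1, xs), y)
    return(fit$coefficients[-1])
  }
  if (p == 1L) {
    # soft threshold: columns have unit population variance
    rho <- sum(xs[, 1] * yc) / n
    return(sign(rho) * max(abs(rho) - alpha, 0))
  }
  fit <- glmnet::glmnet(
    xs, y,
    family = "gaussian", alpha = 1, lambda = alpha,
    standardize = FALSE, intercept = TRUE,
    thresh = 1e-16, maxit = 1e7
  )
  as.numeric(fit$beta[, 1])
}

#' @method print lasso_selection
#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf(
    "<lasso_selection> dimension \"%s\": %d/%d items at alpha = %.4g (training R2 = %.3f)\n",
    x$dimension, length(x$included_items), length(x$coefficients),
    x$alpha, x$training_r2
  ))
  invisible(x)
}

#' Union of items selected across dimensions
#'
#' Step 2 begins by pooling the items retained for any dimension, in original
#' item order. For a unidimensional measure this is the selection itself.
#'
#' @param selections A list of [select_items_lasso()] results (a single
#'   selection is also accepted).
#' @return Character vector of item names in original order.
#' @export
union_included <- function(selections) {
  if (inherits(selections, "lasso_selection")) selections <- list(selections)
  if (!is.list(selections) || length(selections) == 0L) {
    abort("`selections` must be a non-empty list of lasso selections.")
  }
  item_order <- names(selections[[1]]$coefficients)
  included <- unique(unlist(lapply(selections, function(s) s$included_items)))
  item_order[item_order %in% included]
}

#' Refit the pooled items without regularization
#'
#' Step 2 proper: ordinary-least-squares regressions of every target dimension
#' on the pooled item set, fitted on raw (unstandardized) responses so the
#' exported weights apply directly to raw item codes. Items outside the pool
#' have implicit weight zero.
#'
#' @param data Participants x items training responses.
#' @param targets Training target scores: tibble/matrix with one column per
#'   dimension, or a numeric vector for one dimension.
#' @param included Character vector of pooled item names (from
#'   [union_included()]).
#' @param alphas Optional named per-dimension regularization strengths to
#'   record in the model (bookkeeping only; the refit itself is unpenalized).
#' @return An `item_model`: `included_items`, `weights` (included items x
#'   dimensions), `intercepts`, `training_r2`, `alphas_used`, `n_items_total`,
#'   `item_names`.
#' @export
#' @examples
#' dat <- simulate_likert(likert_preset("unidim"), n = 200, seed = 1)
#' y <- sum_scores(dat$responses)
#' m <- refit_union(dat$responses, y, included = names(dat$responses)[1:4])
#' m
refit_union <- function(data, targets, included, alphas = NULL) {
  x <- as_response_matrix(data)
  y <- as_target_matrix(targets, n_rows = nrow(x))
  if (length(included) == 0L) {
    abort("`included` is empty: no item survived selection. Lower `alpha`.")
  }
  missing_items <- setdiff(included, colnames(x))
  if (length(missing_items) > 0) {
    abort(sprintf(
      "Included items absent from the data: %s.",
      paste(missing_items, collapse = ", ")
    ))
  }
  if (nrow(x) <= length(included)) {
    abort("Need more participants than included items for the unregularized refit.")
  }
  xi <- cbind(`(Intercept)` = 1, x[, included, drop = FALSE])
  fit <- lm.fit(xi, y)
  coefs <- as.matrix(fit$coefficients)
  if (anyNA(coefs)) {
    warn("Rank-deficient refit; using the minimum-norm least-squares solution.")
    coefs <- minimum_norm_lsq(xi, y)
  }
  dimnames(coefs) <- list(c("(Intercept)", included), colnames(y))
  fitted <- xi %*% coefs
  r2 <- vapply(
    seq_len(ncol(y)),
    function(j) r_squared(y[, j], fitted[, j]),
    numeric(1)
  )
  if (!is.null(alphas)) {
    alphas <- stats::setNames(as.numeric(alphas), colnames(y))
  }
  structure(
    list(
      included_items = included,
      weights = coefs[-1, , drop = FALSE],
      intercepts = stats::setNames(coefs[1, ], colnames(y)),
      training_r2 = stats::setNames(r2, colnames(y)),
      alphas_used = alphas,
      n_items_total = ncol(x),
      item_names = colnames(x)
    ),
    class = "item_model"
  )
}

minimum_norm_lsq <- function(a, b) {
  s <- svd(a)
  tol <- max(dim(a)) * max(s$d) * .Machine$double.eps
  dinv <- ifelse(s$d > tol, 1 / s$d, 0)
  s$v %*% (dinv * (t(s$u) %*% b))
}

#' Fit a reduced model in one call
#'
#' Runs the full two-step procedure for a fixed vector of per-dimension
#' regularization strengths: Lasso selection per dimension, union of the
#' selected items, and the unregularized refit.
#'
#' @inheritParams refit_union
#' @param alphas Numeric vector of regularization strengths, recycled to the
#'   number of target dimensions.
#' @return An `item_model`, or `NULL` (with a message) when no item survives
#'   selection for any dimension.
#' @export
#' @examples
#' dat <- simulate_likert(likert_preset("sticsa_like"), n = 300, seed = 1)
#' m <- fit_facsimile(dat$responses, sum_scores(dat$responses), alphas = 2)
#' glance(m)
fit_facsimile <- function(data, targets, alphas) {
  x <- as_response_matrix(data)
  y <- as_target_matrix(targets, n_rows = nrow(x))
  d <- ncol(y)
  alphas <- rep_len(as.numeric(alphas), d)
  selections <- lapply(seq_len(d), function(j) {
    select_items_lasso(x, y[, j], alpha = alphas[j], dimension = colnames(y)[j])
  })
  included <- union_included(selections)
  if (length(included) == 0L) {
    inform("No item selected for any dimension at these alphas; returning NULL.")
    return(NULL)
  }
  model <- refit_union(x, y, included, alphas = stats::setNames(alphas, colnames(y)))
  model$selections <- selections
  model
}

#' Smallest regularization strength that empties the model
#'
#' For each target dimension, the closed-form Lasso null threshold
#' `max_j |z_j' (y - mean(y))| / n` over z-scored items `z_j`: at or above
#' this strength every item weight is zero. Useful for choosing the scale of
#' the randomized search so the draws span a measure's whole regularization
#' path — the appropriate scale depends on the measure's length and internal
#' consistency.
#'
#' @inheritParams refit_union
#' @return Named numeric vector, one threshold per target dimension.
#' @export
#' @examples
#' dat <- simulate_likert(likert_preset("unidim"), n = 200, seed = 1)
#' alpha_upper_bound(dat$responses, sum_scores(dat$responses))
alpha_upper_bound <- function(data, targets) {
  x <- as_response_matrix(data)
  y <- as_target_matrix(targets, n_rows = nrow(x))
  mu <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2, mu)^2))
  keep <- sds > 0
  zs <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sds[keep], "/")
  yc <- sweep(y, 2, colMeans(y))
  apply(abs(crossprod(zs, yc)) / nrow(x), 2, max)
}

#' Fit a k-item model along a deterministic Lasso path
#'
#' For a single target dimension the two-step procedure is deterministic in
#' the regularization strength: each strength yields one item subset, so each
#' achievable item count corresponds to one model, and the k-item model can
#' be found by bisection on the strength — no randomized search needed. For
#' several dimensions this walks the one-parameter path
#' `alphas = t * alpha_upper_bound(...)` (a common multiplier of the
#' per-dimension null thresholds), bisecting `t` until the pooled item set
#' has exactly `k` items, then refits without regularization as usual.
#'
#' @inheritParams refit_union
#' @param targets Target scores (one or more dimensions).
#' @param k Desired number of pooled retained items, `1 <= k <` item count.
#' @param max_iter Bisection iterations (default 60).
#' @return An `item_model` with `k` included items. Errors if no strength on
#'   the path yields exactly `k` items (counts can occasionally skip a value
#'   where several correlated items enter or leave together).
#' @export
#' @examples
#' dat <- simulate_likert(likert_preset("unidim"), n = 300, seed = 1)
#' m <- fit_k_items(dat$responses, sum_scores(dat$responses), k = 3)
#' glance(m)
fit_k_items <- function(data, targets, k, max_iter = 60L) {
  x <- as_response_matrix(data)
  y <- as_target_matrix(targets, n_rows = nrow(x))
  check_scalar_number(k, "k", min = 1)
  k <- as.integer(k)
  if (k >= ncol(x)) {
    abort("`k` must be smaller than the number of items.")
  }
  ub <- alpha_upper_bound(x, y) * (1 + 1e-8)
  lo <- 0
  hi <- 1
  best <- NULL
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    sels <- lapply(seq_len(ncol(y)), function(j) {
      select_items_lasso(x, y[, j], alpha = mid * ub[j], dimension = colnames(y)[j])
    })
    included <- union_included(sels)
    n_inc <- length(included)
    if (n_inc == k) {
      best <- list(included = included, alphas = mid * ub)
      break
    } else if (n_inc > k) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  if (is.null(best)) {
    abort(sprintf(
      "No regularization strength on the path yields exactly %d items (the count jumps past it).",
      k
    ))
  }
  refit_union(x, y, best$included, alphas = best$alphas)
}

#' Predict scores from a reduced model
#'
#' Applies the linear weights to the included items:
#' `predicted = responses[, included] %*% weights + intercepts`. Columns for
#' excluded items are ignored (their weight is implicitly zero), so extra
#' columns never change predictions.
#'
#' @param object An `item_model`.
#' @param newdata Participants x items responses containing every included
#'   item column.
#' @param ... Unused.
#' @return A tibble of predicted scores, one column per target dimension.
#' @export
predict.item_model <- function(object, newdata, ...) {
  x <- as_response_matrix(newdata, arg = "newdata")
  absent <- setdiff(object$included_items, colnames(x))
  if (length(absent) > 0) {
    abort(sprintf(
      "Responses are missing included item columns: %s.",
      paste(absent, collapse = ", ")
    ))
  }
  pred <- x[, object$included_items, drop = FALSE] %*% object$weights
  pred <- sweep(pred, 2, object$intercepts, "+")
  tibble::as_tibble(matrix(pred, nrow = nrow(x), dimnames = list(NULL, colnames(pred))))
}

#' @method print item_model
#' @export
print.item_model <- function(x, ...) {
  cat(sprintf(
    "<item_model> %d of %d items -> %d dimension%s (%s)\n",
    length(x$included_items), x$n_items_total,
    length(x$intercepts), if (length(x$intercepts) > 1) "s" else "",
    paste(names(x$intercepts), collapse = ", ")
  ))
  cat(sprintf(
    "  training R2: %s\n",
    paste(sprintf("%s = %.3f", names(x$training_r2), x$training_r2), collapse = ", ")
  ))
  invisible(x)
}

#' Tidy a reduced model's weights
#'
#' @param x An `item_model`.
#' @param ... Unused.
#' @return A tibble with one row per (included item, dimension): `item`,
#'   `dimension`, `weight`.
#' @export
tidy.item_model <- function(x, ...) {
  tibble::tibble(
    item = rep(rownames(x$weights), times = ncol(x$weights)),
    dimension = rep(colnames(x$weights), each = nrow(x$weights)),
    weight = as.vector(x$weights)
  )
}

#' @rdname tidy.item_model
#' @return For `glance()`: a one-row tibble with `n_included`,
#'   `n_items_total`, `min_training_r2`.
#' @export
glance.item_model <- function(x, ...) {
  tibble::tibble(
    n_included = length(x$included_items),
    n_items_total = x$n_items_total,
    n_dimensions = length(x$intercepts),
    min_training_r2 = min(x$training_r2)
  )
}
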