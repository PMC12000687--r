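#' Draw per-dimension regularization strengths
#'
#' Random-search proposal: each dimension's strength is an independent
#' Beta(1, 3) variate multiplied by `scale`. Beta(1, 3) over-samples small
#' values, which tend to be the useful region of the regularization path; the
#' scale adapts the draws to the size of the measure (8 suits a ~22-item
#' scale with sum-score-sized targets).
#'
#' @param n_dims Number of target dimensions.
#' @param scale Positive multiplier applied to the Beta draws.
#' @param shape Beta shape parameters, default `c(1, 3)`.
#' @return Numeric vector of `n_dims` values in `[0, scale]`. Uses the
#'   current RNG stream (seed it with [set.seed()] or [withr::with_seed()]).
#' @export
#' @examples
#' withr::with_seed(1, draw_alphas(2, scale = 8))
draw_alphas <- function(n_dims, scale = 8, shape = c(1, 3)) {
  check_scalar_number(n_dims, "n_dims", min = 1)
  check_scalar_number(scale, "scale", min = .Machine$double.eps)
  scale * rbeta(n_dims, shape[1], shape[2])
}

#' Brevity/accuracy selection score
#'
#' Scores a candidate model as `min(r2_by_dim) * (1 - n_included / n_total)`:
#' the worst-dimension validation accuracy discounted by the proportion of
#' the original items the model keeps. Taking the minimum across dimensions
#' prevents a model that is accurate on average but poor on one dimension
#' from looking good. The score can be negative when the minimum R-squared is
#' negative, and is zero when all items are retained.
#'
#' @param r2_by_dim Numeric vector of per-dimension validation R-squared.
#' @param n_included Number of items the candidate retains.
#' @param n_total Number of items in the original measure.
#' @return A single numeric score.
#' @export
#' @examples
#' selection_score(c(0.9, 0.8), n_included = 10, n_total = 22)
selection_score <- function(r2_by_dim, n_included, n_total) {
  if (!is.numeric(r2_by_dim) || length(r2_by_dim) < 1L) {
    abort("`r2_by_dim` must contain at least one dimension's R-squared.")
  }
  check_scalar_number(n_total, "n_total", min = 1)
  check_scalar_number(n_included, "n_included", min = 0)
  if (n_included > n_total) {
    abort("`n_included` cannot exceed `n_total`.")
  }
  min(r2_by_dim) * (1 - n_included / n_total)
}

#' Randomized search over regularization strengths
#'
#' Repeats the two-step fit ([fit_facsimile()]) for `n_iterations` random
#' draws of per-dimension regularization strengths, evaluating each candidate
#' on a held-out validation set. The result is a frontier of candidate short
#' forms trading brevity against accuracy.
#'
#' @param train Training responses (participants x items).
#' @param train_targets Training target scores (tibble/matrix, one column per
#'   dimension).
#' @param validation Validation responses with the same item columns.
#' @param validation_targets Validation target scores with the same
#'   dimensions.
#' @param n_iterations Number of random draws (default 1000).
#' @param scale,shape Passed to [draw_alphas()].
#' @param seed Integer seed for the whole search; `NULL` uses the current RNG
#'   stream.
#' @return A `facsimile_frontier`: a tibble with one row per retained
#'   candidate — `iteration`, one `alpha_*` and one `r2_*` column per
#'   dimension, `n_included`, `r2_min`, `score` — and a `model` list-column of
#'   `item_model` objects. Draws whose pooled item set is empty are dropped
#'   (count reported in attribute `n_empty_dropped`).
#' @export
#' @examples
#' dat <- simulate_likert(likert_preset("unidim"), n = 300, seed = 1)
#' idx <- split_data(300, seed = 1)
#' y <- sum_scores(dat$responses)
#' fr <- run_search(
#'   dat$responses[idx$train, ], y[idx$train, ],
#'   dat$responses[idx$validation, ], y[idx$validation, ],
#'   n_iterations = 25, scale = 4, seed = 2
#' )
#' frontier_curve(fr)
run_search <- function(train, train_targets, validation, validation_targets,
                       n_iterations = 1000, scale = 8, shape = c(1, 3),
                       seed = NULL) {
  xt <- as_response_matrix(train, arg = "train")
  yt <- as_target_matrix(train_targets, n_rows = nrow(xt), arg = "train_targets")
  xv <- as_response_matrix(validation, arg = "validation")
  yv <- as_target_matrix(validation_targets, n_rows = nrow(xv), arg = "validation_targets")
  if (!identical(colnames(xt), colnames(xv))) {
    abort("`train` and `validation` must share identical item columns.")
  }
  if (!identical(colnames(yt), colnames(yv))) {
    abort("`train_targets` and `validation_targets` must share identical dimensions.")
  }
  check_scalar_number(n_iterations, "n_iterations", min = 1)
  d <- ncol(yt)
  dims <- colnames(yt)

  rows <- with_seed_or_current(seed, {
    lapply(seq_len(n_iterations), function(it) {
      alphas <- draw_alphas(d, scale = scale, shape = shape)
      model <- fit_facsimile(xt, yt, alphas = alphas)
      if (is.null(model)) {
        return(NULL)
      }
      pred <- predict(model, xv)
      r2 <- vapply(seq_len(d), function(j) r_squared(yv[, j], pred[[j]]), numeric(1))
      n_inc <- length(model$included_items)
      list(
        iteration = it, alphas = alphas, model = model, r2 = r2,
        n_included = n_inc,
        score = selection_score(r2, n_inc, ncol(xt))
      )
    })
  })
  n_empty <- sum(vapply(rows, is.null, logical(1)))
  if (n_empty > 0) {
    inform(sprintf("%d draw(s) selected no items and were dropped.", n_empty))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    abort("Every draw selected no items; lower `scale`.")
  }

  alpha_mat <- do.call(rbind, lapply(rows, `[[`, "alphas"))
  r2_mat <- do.call(rbind, lapply(rows, `[[`, "r2"))
  colnames(alpha_mat) <- paste0("alpha_", dims)
  colnames(r2_mat) <- paste0("r2_", dims)
  out <- tibble::tibble(
    iteration = vapply(rows, `[[`, integer(1), "iteration"),
    !!!tibble::as_tibble(alpha_mat),
    n_included = vapply(rows, `[[`, integer(1), "n_included"),
    !!!tibble::as_tibble(r2_mat),
    r2_min = apply(r2_mat, 1, min),
    score = vapply(rows, `[[`, numeric(1), "score"),
    model = lapply(rows, `[[`, "model")
  )
  structure(
    out,
    class = c("facsimile_frontier", class(out)),
    dimensions = dims,
    n_items_total = ncol(xt),
    n_iterations = as.integer(n_iterations),
    n_empty_dropped = n_empty,
    scale = scale,
    shape = shape,
    seed = seed
  )
}

#' Pick the best candidate from a search frontier
#'
#' Maximizes the brevity/accuracy [selection_score()]; ties are broken in
#' favour of fewer items, then the earlier iteration. Alternative criteria
#' (`"items"`, `"r2"`) select the most accurate candidate at a fixed size, or
#' the smallest candidate reaching an accuracy floor.
#'
#' @param frontier A `facsimile_frontier` from [run_search()].
#' @param criterion `"score"` (default), `"items"` or `"r2"`.
#' @param value For `criterion = "items"`, the exact retained-item count; for
#'   `criterion = "r2"`, the minimum acceptable worst-dimension validation
#'   R-squared.
#' @return The winning one-row frontier record (use `$model[[1]]` for the
#'   fitted `item_model`).
#' @export
best_model <- function(frontier, criterion = c("score", "items", "r2"), value = NULL) {
  if (!inherits(frontier, "facsimile_frontier") || nrow(frontier) == 0L) {
    abort("`frontier` must be a non-empty `facsimile_frontier`.")
  }
  criterion <- match.arg(criterion)
  records <- frontier
  if (criterion == "items") {
    check_scalar_number(value, "value", min = 1)
    records <- dplyr::filter(records, .data$n_included == value)
    if (nrow(records) == 0L) {
      abort(sprintf("No candidate retains exactly %d items.", as.integer(value)))
    }
    records <- dplyr::arrange(records, dplyr::desc(.data$r2_min), .data$iteration)
  } else if (criterion == "r2") {
    check_scalar_number(value, "value")
    records <- dplyr::filter(records, .data$r2_min >= value)
    if (nrow(records) == 0L) {
      abort(sprintf("No candidate reaches a minimum validation R-squared of %.3f.", value))
    }
    records <- dplyr::arrange(records, .data$n_included, dplyr::desc(.data$r2_min), .data$iteration)
  } else {
    records <- dplyr::arrange(
      records,
      dplyr::desc(.data$score), .data$n_included, .data$iteration
    )
  }
  dplyr::slice(records, 1L)
}

#' Brevity/accuracy frontier curve
#'
#' For each observed retained-item count, the best (maximum) worst-dimension
#' validation R-squared across candidates — the curve relating measure length
#' to accuracy.
#'
#' @param frontier A `facsimile_frontier` from [run_search()].
#' @return A tibble with columns `n_included`, `r2` (best min-dimension
#'   validation R-squared), `iteration` (of the best candidate) and
#'   `n_candidates`.
#' @export
frontier_curve <- function(frontier) {
  if (!inherits(frontier, "facsimile_frontier") || nrow(frontier) == 0L) {
    abort("`frontier` must be a non-empty `facsimile_frontier`.")
  }
  frontier |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$n_included) |>
    dplyr::summarise(
      r2 = max(.data$r2_min),
      iteration = .data$iteration[which.max(.data$r2_min)],
      n_candidates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$n_included)
}

#' @method print facsimile_frontier
#' @export
print.facsimile_frontier <- function(x, ...) {
  cat(sprintf(
    "<facsimile_frontier> %d candidate models over %d iterations (%d empty draws dropped)\n",
    nrow(x), attr(x, "n_iterations"), attr(x, "n_empty_dropped")
  ))
  cat(sprintf(
    "  dimensions: %s | items: %d | alpha scale: %s\n",
    paste(attr(x, "dimensions"), collapse = ", "),
    attr(x, "n_items_total"), format(attr(x, "scale"))
  ))
  print(tibble::as_tibble(dplyr::select(x, -"model")), n = 5)
  invisible(x)
}

#' @rdname run_search
#' @param x A `facsimile_frontier`.
#' @param ... Unused.
#' @export
tidy.facsimile_frontier <- function(x, ...) {
  tibble::as_tibble(dplyr::select(tibble::as_tibble(x), -"model"))
}

#' @rdname run_search
#' @export
glance.facsimile_frontier <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_iterations = attr(x, "n_iterations"),
    n_empty_dropped = attr(x, "n_empty_dropped"),
    n_items_total = attr(x, "n_items_total"),
    best_score = max(x$score)
  )
}
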