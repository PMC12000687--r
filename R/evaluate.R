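#' Train/validation/test partition
#'
#' Partitions `n` participants by a seeded permutation. The validation and
#' test sizes are the ceiling of `n` times their proportions and training
#' receives the remainder, so 1622 participants at proportions (0.6, 0.2,
#' 0.2) give 972/325/325.
#'
#' @param n Number of participants.
#' @param proportions Length-3 numeric vector (train, validation, test)
#'   summing to 1.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A `split_spec`: list with integer row-index vectors `train`,
#'   `validation`, `test`, plus `sizes`, `proportions`, `seed`.
#' @export
#' @examples
#' split_data(1622, c(0.6, 0.2, 0.2), seed = 1)$sizes
split_data <- function(n, proportions = c(train = 0.6, validation = 0.2, test = 0.2),
                       seed = NULL) {
  check_scalar_number(n, "n", min = 3)
  n <- as.integer(n)
  if (length(proportions) != 3L || any(proportions < 0)) {
    abort("`proportions` must be three non-negative numbers (train, validation, test).")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("`proportions` must sum to 1.")
  }
  n_validation <- as.integer(ceiling(n * proportions[2]))
  n_test <- as.integer(ceiling(n * proportions[3]))
  n_train <- n - n_validation - n_test
  sizes <- c(train = n_train, validation = n_validation, test = n_test)
  if (any(sizes <= 0L)) {
    abort(sprintf(
      "Partition sizes (%s) must all be positive; adjust `proportions` or `n`.",
      paste(sizes, collapse = ", ")
    ))
  }
  perm <- with_seed_or_current(seed, sample.int(n))
  structure(
    list(
      train = sort(perm[seq_len(n_train)]),
      validation = sort(perm[n_train + seq_len(n_validation)]),
      test = sort(perm[n_train + n_validation + seq_len(n_test)]),
      sizes = sizes,
      proportions = proportions,
      seed = seed
    ),
    class = "split_spec"
  )
}

#' @method print split_spec
#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf(
    "<split_spec> train %d / validation %d / test %d\n",
    x$sizes["train"], x$sizes["validation"], x$sizes["test"]
  ))
  invisible(x)
}

#' Coefficient of determination
#'
#' `1 - RSS/TSS`, with the total sum of squares taken about the observed
#' mean. Can be negative when predictions do worse than the observed mean.
#'
#' @param observed Numeric vector of observed scores (must have non-zero
#'   variance).
#' @param predicted Numeric vector of predictions, same length.
#' @return A single numeric value.
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))
r_squared <- function(observed, predicted) {
  if (!is.numeric(observed) || !is.numeric(predicted)) {
    abort("`observed` and `predicted` must be numeric vectors.")
  }
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal lengths.")
  }
  if (length(observed) < 2L) {
    abort("At least 2 observations are required.")
  }
  tss <- sum((observed - mean(observed))^2)
  if (tss <= 0) {
    abort("`observed` has zero variance; R-squared is undefined.")
  }
  1 - sum((observed - predicted)^2) / tss
}

#' Evaluate a reduced model on held-out data
#'
#' Computes per-dimension R-squared between observed and predicted scores,
#' keeping the predicted/observed pairs for scatter plots.
#'
#' @param model An `item_model`.
#' @param data Held-out responses containing the included item columns.
#' @param targets Held-out target scores with the model's dimensions.
#' @return A `facsimile_eval`: tibble with columns `dimension` and `r2`;
#'   attribute `predictions` holds a long tibble (`dimension`, `observed`,
#'   `predicted`).
#' @export
#' @examples
#' dat <- simulate_likert(likert_preset("unidim"), n = 100, seed = 1)
#' y <- sum_scores(dat$responses)
#' m <- fit_facsimile(dat$responses, y, alphas = 0.5)
#' evaluate_model(m, dat$responses, y)
evaluate_model <- function(model, data, targets) {
  if (!inherits(model, "item_model")) abort("`model` must be an `item_model`.")
  x <- as_response_matrix(data)
  y <- as_target_matrix(targets, n_rows = nrow(x))
  dims <- names(model$intercepts)
  if (!identical(colnames(y), dims)) {
    abort(sprintf(
      "Target dimensions (%s) do not match the model's (%s).",
      paste(colnames(y), collapse = ", "), paste(dims, collapse = ", ")
    ))
  }
  pred <- predict(model, x)
  r2 <- vapply(dims, function(d) r_squared(y[, d], pred[[d]]), numeric(1))
  out <- tibble::tibble(dimension = dims, r2 = unname(r2))
  attr(out, "predictions") <- tibble::tibble(
    dimension = rep(dims, each = nrow(x)),
    observed = as.vector(y[, dims]),
    predicted = unlist(pred[dims], use.names = FALSE)
  )
  class(out) <- c("facsimile_eval", class(out))
  out
}

#' Sample-size sensitivity bootstrap
#'
#' How does training sample size affect achievable accuracy? For each sample
#' size, `n_boot` subsamples are drawn with replacement from the training
#' pool; the randomized search is run on each subsample (every candidate
#' trained on the whole subsample) and each candidate is scored on the fixed
#' held-out evaluation set, so curves are comparable across sizes. Results
#' are aggregated per (sample size, retained-item count) as the mean and the
#' 2.5/97.5 percentile band of the best worst-dimension R-squared.
#'
#' @param train Training-pool responses.
#' @param train_targets Training-pool target scores.
#' @param eval_data Fixed held-out responses used to score every candidate.
#' @param eval_targets Held-out target scores.
#' @param sample_sizes Training sizes to probe (default 50–500 as in the
#'   sensitivity analysis this mirrors).
#' @param n_boot Subsamples per size (default 1000; scale down for quick
#'   looks).
#' @param n_iterations Random-search iterations per subsample (default 100; a
#'   reduced budget keeps the bootstrap tractable).
#' @param scale,shape Passed to [draw_alphas()].
#' @param seed Integer seed for the whole bootstrap.
#' @return A `sample_size_curve` tibble: `sample_size`, `n_included`,
#'   `mean_r2`, `lower`, `upper` (95% percentile band), `n_models`; attribute
#'   `draws` holds the per-subsample table.
#' @export
sample_size_curve <- function(train, train_targets, eval_data, eval_targets,
                              sample_sizes = c(50, 100, 200, 300, 400, 500),
                              n_boot = 1000, n_iterations = 100,
                              scale = 8, shape = c(1, 3), seed = NULL) {
  xt <- as_response_matrix(train, arg = "train")
  yt <- as_target_matrix(train_targets, n_rows = nrow(xt), arg = "train_targets")
  if (any(sample_sizes > nrow(xt))) {
    abort(sprintf(
      "Sample sizes exceed the training pool (%d rows): %s.",
      nrow(xt), paste(sample_sizes[sample_sizes > nrow(xt)], collapse = ", ")
    ))
  }
  check_scalar_number(n_boot, "n_boot", min = 1)

  draws <- with_seed_or_current(seed, {
    purrr::map_dfr(sample_sizes, function(size) {
      purrr::map_dfr(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(xt), size, replace = TRUE)
        fr <- suppressMessages(run_search(
          xt[idx, , drop = FALSE], yt[idx, , drop = FALSE],
          eval_data, eval_targets,
          n_iterations = n_iterations, scale = scale, shape = shape,
          seed = NULL
        ))
        fc <- frontier_curve(fr)
        tibble::tibble(
          sample_size = size, boot = b,
          n_included = fc$n_included, r2 = fc$r2
        )
      })
    })
  })

  out <- draws |>
    dplyr::group_by(.data$sample_size, .data$n_included) |>
    dplyr::summarise(
      mean_r2 = mean(.data$r2),
      lower = unname(quantile(.data$r2, 0.025)),
      upper = unname(quantile(.data$r2, 0.975)),
      n_models = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "draws") <- draws
  attr(out, "n_boot") <- as.integer(n_boot)
  attr(out, "seed") <- seed
  class(out) <- c("sample_size_curve", class(out))
  out
}
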