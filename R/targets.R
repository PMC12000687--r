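#' Total sum scores
#'
#' The simplest prediction target: the unweighted sum of every item response
#' per participant.
#'
#' @param data Participants x items data frame (or matrix) of numeric item
#'   responses.
#' @param na_impute Replace missing cells by the item mean before summing.
#'   Off by default: missing data are rejected with an error.
#' @return A tibble with a single column `total`, one row per participant,
#'   carrying attribute `kind = "sum"`.
#' @export
#' @examples
#' dat <- simulate_likert(likert_preset("unidim"), n = 20, seed = 1)
#' sum_scores(dat$responses)
sum_scores <- function(data, na_impute = FALSE) {
  x <- as_response_matrix(data)
  x <- handle_missing(x, na_impute)
  out <- tibble::tibble(total = rowSums(x))
  attr(out, "kind") <- "sum"
  out
}

#' Subscale sum scores
#'
#' Row sums over pre-defined item subsets (e.g. cognitive vs. somatic anxiety
#' subscales). Every item must be assigned to exactly one subscale.
#'
#' @inheritParams sum_scores
#' @param assignment Either a named character vector (`item -> subscale`) or a
#'   two-column data frame with columns `item` and `subscale`.
#' @return A tibble with one column per subscale, attribute `kind = "subscale"`.
#' @export
#' @examples
#' dat <- simulate_likert(likert_preset("sticsa_like"), n = 20, seed = 1)
#' items <- names(dat$responses)
#' assignment <- setNames(rep(c("cognitive", "somatic"), each = 11), items)
#' subscale_scores(dat$responses, assignment)
subscale_scores <- function(data, assignment, na_impute = FALSE) {
  x <- as_response_matrix(data)
  x <- handle_missing(x, na_impute)
  map <- as_assignment(assignment)
  items <- colnames(x)
  missing_items <- setdiff(items, names(map))
  if (length(missing_items) > 0) {
    abort(sprintf(
      "Items not assigned to any subscale: %s.",
      paste(missing_items, collapse = ", ")
    ))
  }
  extra <- setdiff(names(map), items)
  if (length(extra) > 0) {
    abort(sprintf(
      "Assignment names items absent from the data: %s.",
      paste(extra, collapse = ", ")
    ))
  }
  subscales <- unique(unname(map[items]))
  cols <- lapply(subscales, function(s) rowSums(x[, names(map)[map == s], drop = FALSE]))
  names(cols) <- subscales
  out <- tibble::as_tibble(cols)
  attr(out, "kind") <- "subscale"
  out
}

as_assignment <- function(assignment) {
  if (is.data.frame(assignment)) {
    if (!all(c("item", "subscale") %in% names(assignment))) {
      abort("`assignment` data frame must have columns `item` and `subscale`.")
    }
    map <- stats::setNames(as.character(assignment$subscale), as.character(assignment$item))
  } else if (is.character(assignment) && !is.null(names(assignment))) {
    map <- assignment
  } else {
    abort("`assignment` must be a named character vector or an item/subscale data frame.")
  }
  dup <- names(map)[duplicated(names(map))]
  if (length(dup) > 0) {
    abort(sprintf("Items assigned more than once: %s.", paste(unique(dup), collapse = ", ")))
  }
  map
}

handle_missing <- function(x, na_impute) {
  if (!anyNA(x)) {
    return(x)
  }
  if (!na_impute) {
    bad <- which(colSums(is.na(x)) > 0)
    abort(sprintf(
      "Missing responses in items: %s. Set `na_impute = TRUE` for per-item mean imputation.",
      paste(colnames(x)[bad], collapse = ", ")
    ))
  }
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  x
}

#' Exploratory factor analysis with oblimin rotation
#'
#' Fits a maximum-likelihood common-factor model to the item Pearson
#' correlation matrix, applies an oblique oblimin (quartimin) rotation, and
#' computes factor scores by the regression (Thurstone) method. The
#' eigenvalues of the item correlation matrix are retained for scree
#' inspection and factor-count heuristics.
#'
#' @inheritParams sum_scores
#' @param n_factors Number of common factors to extract; must be at least 1
#'   and smaller than the number of items.
#' @return An object of class `efa_fit` with elements `loadings` (rotated
#'   pattern matrix), `factor_correlation`, `uniquenesses`, `eigenvalues`
#'   (descending, one per item), `scores` (tibble of regression-method factor
#'   scores) and `n_factors`.
#' @export
#' @examples
#' dat <- simulate_likert(likert_preset("sticsa_like"), n = 500, seed = 1)
#' efa <- fit_efa(dat$responses, n_factors = 2)
#' efa
fit_efa <- function(data, n_factors, na_impute = FALSE) {
  x <- as_response_matrix(data)
  x <- handle_missing(x, na_impute)
  p <- ncol(x)
  check_scalar_number(n_factors, "n_factors", min = 1)
  n_factors <- as.integer(n_factors)
  if (n_factors >= p) {
    abort("`n_factors` must be smaller than the number of items.")
  }
  if (nrow(x) <= p) {
    abort("EFA needs more participants than items.")
  }
  r <- stats::cor(x)
  eigenvalues <- sort(eigen(r, symmetric = TRUE, only.values = TRUE)$values,
    decreasing = TRUE
  )
  fa <- tryCatch(
    stats::factanal(covmat = r, factors = n_factors, n.obs = nrow(x), rotation = "none"),
    error = function(e) {
      abort(sprintf(
        "Maximum-likelihood factor extraction failed to converge (%s).",
        conditionMessage(e)
      ), parent = e)
    }
  )
  unrot <- matrix(fa$loadings, nrow = p, dimnames = list(colnames(x), NULL))
  if (n_factors == 1L) {
    lam <- unrot
    phi <- matrix(1, 1, 1)
  } else {
    rot <- rotate_oblimin(unrot)
    lam <- rot$loadings
    phi <- rot$phi
  }
  colnames(lam) <- paste0("factor_", seq_len(n_factors))
  dimnames(phi) <- list(colnames(lam), colnames(lam))

  # Regression (Thurstone) factor scores: standardized responses times
  # R^-1 S, where S = Lambda Phi is the structure matrix.
  structure_mat <- lam %*% phi
  w <- solve(r, structure_mat)
  z <- scale(x)
  scores <- z %*% w
  structure(
    list(
      loadings = lam,
      factor_correlation = phi,
      uniquenesses = fa$uniquenesses,
      eigenvalues = eigenvalues,
      scores = tibble::as_tibble(
        matrix(scores, nrow = nrow(x), dimnames = list(NULL, colnames(lam)))
      ),
      n_factors = n_factors,
      n_obs = nrow(x)
    ),
    class = "efa_fit"
  )
}

#' Extract factor scores as a prediction target
#'
#' @param efa An [fit_efa()] result.
#' @return A tibble of regression-method factor scores, attribute
#'   `kind = "factor"`.
#' @export
factor_scores <- function(efa) {
  if (!inherits(efa, "efa_fit")) abort("`efa` must be an `efa_fit` object.")
  out <- efa$scores
  attr(out, "kind") <- "factor"
  out
}

#' Choose the number of factors from eigenvalues
#'
#' Operational scree rule: retain the count of correlation-matrix eigenvalues
#' exceeding 1 (Kaiser criterion). The full eigenvalue sequence from
#' [fit_efa()] (or [scree_eigenvalues()]) supports a human override via an
#' explicit `n_factors` argument downstream.
#'
#' @param eigenvalues Numeric vector of correlation-matrix eigenvalues.
#' @return Integer count of eigenvalues above 1; warns when the count is zero.
#' @export
#' @examples
#' choose_n_factors(c(5.0, 0.9, 0.5))
choose_n_factors <- function(eigenvalues) {
  if (!is.numeric(eigenvalues) || length(eigenvalues) < 1L) {
    abort("`eigenvalues` must be a non-empty numeric vector.")
  }
  k <- sum(eigenvalues > 1)
  if (k == 0L) {
    warn("No eigenvalue exceeds 1; the data indicate no common factor.")
  }
  as.integer(k)
}

#' Eigenvalues of the item correlation matrix
#'
#' @inheritParams sum_scores
#' @return Numeric vector of eigenvalues in decreasing order, one per item.
#' @export
scree_eigenvalues <- function(data) {
  x <- as_response_matrix(data)
  sort(eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values,
    decreasing = TRUE
  )
}

#' @method print efa_fit
#' @export
print.efa_fit <- function(x, ...) {
  cat(sprintf(
    "<efa_fit> %d-factor maximum-likelihood solution, oblimin rotation (n = %d)\n",
    x$n_factors, x$n_obs
  ))
  cat("Rotated loadings:\n")
  print(round(x$loadings, 3))
  if (x$n_factors > 1) {
    cat("Factor correlations:\n")
    print(round(x$factor_correlation, 3))
  }
  invisible(x)
}

#' @rdname fit_efa
#' @param x,object An `efa_fit` object.
#' @param ... Unused.
#' @export
tidy.efa_fit <- function(x, ...) {
  tibble::tibble(
    item = rep(rownames(x$loadings), times = x$n_factors),
    factor = rep(colnames(x$loadings), each = nrow(x$loadings)),
    loading = as.vector(x$loadings)
  )
}

#' @rdname fit_efa
#' @export
glance.efa_fit <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors,
    n_obs = x$n_obs,
    n_items = nrow(x$loadings),
    kaiser_n_factors = sum(x$eigenvalues > 1),
    prop_variance = sum(1 - x$uniquenesses) / nrow(x$loadings)
  )
}
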