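# Internal helpers shared across modules.

# Coerce a participants x items data frame (or matrix) to a numeric matrix
# with item names, validating shape and numeric content.
as_response_matrix <- function(data, arg = "data") {
  if (is.matrix(data)) {
    x <- data
  } else if (is.data.frame(data)) {
    not_num <- !vapply(data, is.numeric, logical(1))
    if (any(not_num)) {
      abort(sprintf(
        "`%s` has non-numeric columns: %s.",
        arg, paste(names(data)[not_num], collapse = ", ")
      ))
    }
    x <- as.matrix(data)
  } else {
    abort(sprintf("`%s` must be a data frame or matrix of item responses.", arg))
  }
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) {
    colnames(x) <- item_labels(ncol(x))
  }
  if (anyDuplicated(colnames(x))) {
    abort(sprintf(
      "`%s` has duplicated item columns: %s.",
      arg, paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", ")
    ))
  }
  x
}

# Coerce targets (vector, data frame, or matrix) to a numeric matrix with
# one column per dimension.
as_target_matrix <- function(targets, n_rows = NULL, arg = "targets") {
  if (is.numeric(targets) && is.null(dim(targets))) {
    y <- matrix(targets, ncol = 1, dimnames = list(NULL, "target"))
  } else if (is.data.frame(targets) || is.matrix(targets)) {
    y <- as.matrix(targets)
    storage.mode(y) <- "double"
    if (is.null(colnames(y))) {
      colnames(y) <- paste0("dim_", seq_len(ncol(y)))
    }
  } else {
    abort(sprintf("`%s` must be a numeric vector, data frame or matrix.", arg))
  }
  if (!is.null(n_rows) && nrow(y) != n_rows) {
    abort(sprintf(
      "`%s` has %d rows but the response data has %d.", arg, nrow(y), n_rows
    ))
  }
  y
}

item_labels <- function(n) {
  sprintf(paste0("item_%0", max(2L, nchar(n)), "d"), seq_len(n))
}

# Run `expr` under a temporary seed when one is given, otherwise use the
# current RNG stream (so callers can manage reproducibility themselves).
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

check_scalar_number <- function(x, arg, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", arg))
  }
  if (x < min) {
    abort(sprintf("`%s` must be >= %s.", arg, format(min)))
  }
  invisible(x)
}
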