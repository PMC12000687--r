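# Reading and writing the tool's file formats: response CSVs, the
# spreadsheet-oriented weights CSV, and the JSON model file.

#' Read a response CSV
#'
#' Expects a header row of unique item identifiers and one participant per
#' row of numeric (typically integer Likert) codes. Blank cells become `NA`
#' (missing); non-numeric cells, duplicate headers and ragged rows raise
#' errors with coordinates.
#'
#' @param path Path to a comma-separated file (UTF-8, period decimal
#'   separator).
#' @return A tibble of numeric responses, columns in file order.
#' @export
read_responses <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  dup <- unique(header[duplicated(header)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate item identifiers in header: %s.", paste(dup, collapse = ", ")))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, locale = readr::locale(decimal_mark = ".")
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "Malformed rows in %s (first problem: row %d, column %d: %s).",
      path, probs$row[1], probs$col[1], probs$expected[1]
    ))
  }
  out <- raw
  for (j in seq_along(out)) {
    v <- out[[j]]
    blank <- is.na(v) | trimws(v) == ""
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!blank & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-numeric cell at row %d, column \"%s\" (value \"%s\").",
        bad[1], names(out)[j], v[bad[1]]
      ))
    }
    num[blank] <- NA_real_
    out[[j]] <- num
  }
  out
}

#' Write a response CSV
#'
#' @param data Participants x items responses.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(data, path) {
  readr::write_csv(tibble::as_tibble(as_response_matrix(data)), path, progress = FALSE)
  invisible(path)
}

intercept_label <- "(intercept)"

#' Export model weights for spreadsheet scoring
#'
#' Writes a CSV with one row per included item (columns: `item`, one weight
#' column per target dimension) and a final `(intercept)` row, so predicted
#' scores can be computed outside any code: multiply each response by its
#' weight, sum, and add the intercept. Excluded items are omitted — their
#' weight is implicitly zero. Metadata (total item count, dimensions, alphas,
#' tool version) is stored in `#`-prefixed comment lines.
#'
#' @param model An `item_model`.
#' @param path Output path for the CSV.
#' @param seed Optional creation seed recorded in the metadata.
#' @return `path`, invisibly.
#' @export
export_weights <- function(model, path, seed = NULL) {
  if (!inherits(model, "item_model")) abort("`model` must be an `item_model`.")
  dims <- names(model$intercepts)
  tab <- tibble::tibble(item = c(model$included_items, intercept_label))
  for (d in dims) {
    tab[[d]] <- c(model$weights[, d], model$intercepts[[d]])
  }
  meta <- c(
    sprintf("# facsimile weights v%s", as.character(packageVersion("facsimile"))),
    sprintf("# n_items_total: %d", model$n_items_total),
    sprintf("# dimensions: %s", paste(dims, collapse = ";")),
    if (!is.null(model$alphas_used)) {
      sprintf("# alphas: %s", paste(format(model$alphas_used, digits = 10), collapse = ";"))
    },
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed))
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0(meta, "\n"), readr::format_csv(tab)), con, sep = "")
  invisible(path)
}

#' Read an exported weights table
#'
#' @param path Path to a CSV written by [export_weights()].
#' @return A list with `weights` (included items x dimensions matrix),
#'   `intercepts` (named vector) and `metadata` (character vector of comment
#'   lines).
#' @export
read_weights <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  tab <- readr::read_csv(
    I(paste(lines[!startsWith(lines, "#")], collapse = "\n")),
    col_types = readr::cols(item = readr::col_character(), .default = readr::col_double()),
    progress = FALSE
  )
  if (sum(tab$item == intercept_label) != 1L) {
    abort("The weights table must contain exactly one `(intercept)` row.")
  }
  int_row <- tab$item == intercept_label
  w <- as.matrix(tab[!int_row, -1, drop = FALSE])
  rownames(w) <- tab$item[!int_row]
  list(
    weights = w,
    intercepts = unlist(tab[int_row, -1, drop = FALSE]),
    metadata = meta
  )
}

#' Predict scores from an exported weights table
#'
#' Spreadsheet-equivalent scoring: for each participant, sum the included
#' items times their weights and add the intercept. Equivalent to loading the
#' model and calling [predict.item_model()].
#'
#' @param weights Path to a weights CSV, or the list returned by
#'   [read_weights()].
#' @param responses Path to a response CSV, or a responses data frame.
#' @return A tibble of predicted scores, one column per dimension.
#' @export
predict_from_weights <- function(weights, responses) {
  if (is.character(weights)) weights <- read_weights(weights)
  if (is.character(responses)) responses <- read_responses(responses)
  x <- as_response_matrix(responses, arg = "responses")
  items <- rownames(weights$weights)
  absent <- setdiff(items, colnames(x))
  if (length(absent) > 0) {
    abort(sprintf(
      "Responses are missing items listed in the weights table: %s.",
      paste(absent, collapse = ", ")
    ))
  }
  pred <- x[, items, drop = FALSE] %*% weights$weights
  pred <- sweep(pred, 2, weights$intercepts, "+")
  tibble::as_tibble(matrix(pred, nrow = nrow(x), dimnames = list(NULL, colnames(pred))))
}

#' Save / load a reduced model as JSON
#'
#' The JSON file is the model of record (human-inspectable and diff-able);
#' the weights CSV of [export_weights()] is a derived spreadsheet view.
#'
#' @param model An `item_model`.
#' @param path Output path.
#' @return `path` invisibly (`write_model`); an `item_model` (`read_model`).
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "item_model")) abort("`model` must be an `item_model`.")
  payload <- list(
    format = "facsimile_model",
    version = as.character(packageVersion("facsimile")),
    included_items = model$included_items,
    dimensions = names(model$intercepts),
    weights = unclass(as.data.frame(model$weights)),
    intercepts = as.list(model$intercepts),
    training_r2 = as.list(model$training_r2),
    alphas_used = if (is.null(model$alphas_used)) NULL else as.list(model$alphas_used),
    n_items_total = model$n_items_total,
    item_names = model$item_names
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "facsimile_model")) {
    abort(sprintf("%s is not a facsimile model file.", path))
  }
  w <- do.call(cbind, payload$weights[payload$dimensions])
  rownames(w) <- payload$included_items
  structure(
    list(
      included_items = payload$included_items,
      weights = w,
      intercepts = unlist(payload$intercepts[payload$dimensions]),
      training_r2 = unlist(payload$training_r2[payload$dimensions]),
      alphas_used = if (is.null(payload$alphas_used)) NULL else unlist(payload$alphas_used),
      n_items_total = as.integer(payload$n_items_total),
      item_names = payload$item_names
    ),
    class = "item_model"
  )
}
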