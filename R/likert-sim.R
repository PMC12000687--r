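#' Define a synthetic Likert-scale population
#'
#' A `likert_spec` describes a population of questionnaire respondents under a
#' linear common-factor model: each item's latent response is a weighted sum of
#' correlated latent factors plus a normal residual, scaled to unit total
#' variance, and is then discretized through a shared set of ordered thresholds
#' into integer Likert categories (`k` thresholds give `k + 1` categories,
#' coded `1 ... k + 1`).
#'
#' @param loadings Numeric items x factors matrix of factor loadings. Simple
#'   structure (one non-zero loading per row) is allowed but not required.
#' @param factor_correlation Factors x factors correlation matrix: symmetric,
#'   unit diagonal, positive definite. Defaults to the identity.
#' @param thresholds Strictly increasing numeric cut-points applied to the
#'   latent item responses.
#' @param n_respondents Default number of respondents drawn by
#'   [simulate_likert()].
#'
#' @return An object of class `likert_spec`.
#' @seealso [likert_preset()], [simulate_likert()]
#' @export
#' @examples
#' spec <- likert_spec(
#'   loadings = cbind(c(0.8, 0.7, 0.75, 0.85)),
#'   thresholds = c(-1, 0, 1)
#' )
#' spec
likert_spec <- function(loadings,
                        factor_correlation = NULL,
                        thresholds = c(-1, 0, 1),
                        n_respondents = 1000L) {
  loadings <- as.matrix(loadings)
  storage.mode(loadings) <- "double"
  n_items <- nrow(loadings)
  n_factors <- ncol(loadings)
  if (n_items < 1L || n_factors < 1L) {
    abort("`loadings` must have at least one row (item) and one column (factor).")
  }
  if (is.null(factor_correlation)) {
    factor_correlation <- diag(n_factors)
  }
  phi <- as.matrix(factor_correlation)
  if (!isTRUE(all.equal(phi, t(phi), tolerance = 1e-10))) {
    abort("`factor_correlation` must be symmetric.")
  }
  if (!isTRUE(all.equal(unname(diag(phi)), rep(1, n_factors), tolerance = 1e-10))) {
    abort("`factor_correlation` must have a unit diagonal.")
  }
  ev <- eigen(phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort("`factor_correlation` must be positive definite.")
  }
  if (!is.numeric(thresholds) || length(thresholds) < 1L) {
    abort("`thresholds` must be a non-empty numeric vector.")
  }
  if (any(diff(thresholds) <= 0)) {
    abort("`thresholds` must be strictly increasing.")
  }
  communality <- rowSums((loadings %*% phi) * loadings)
  if (any(communality > 1 + 1e-8)) {
    abort(paste0(
      "Item communalities exceed 1 (rows ",
      paste(which(communality > 1 + 1e-8), collapse = ", "),
      "); scale the loadings down."
    ))
  }
  check_scalar_number(n_respondents, "n_respondents", min = 1)
  rownames(loadings) <- item_labels(n_items)
  colnames(loadings) <- paste0("factor_", seq_len(n_factors))
  dimnames(phi) <- list(colnames(loadings), colnames(loadings))
  structure(
    list(
      n_items = n_items,
      n_factors = n_factors,
      loadings = loadings,
      factor_correlation = phi,
      thresholds = as.numeric(thresholds),
      n_categories = length(thresholds) + 1L,
      n_respondents = as.integer(n_respondents)
    ),
    class = "likert_spec"
  )
}

#' @method print likert_spec
#' @export
print.likert_spec <- function(x, ...) {
  cat(sprintf(
    "<likert_spec> %d items, %d factor%s, %d response categories\n",
    x$n_items, x$n_factors, if (x$n_factors > 1) "s" else "", x$n_categories
  ))
  cat(sprintf(
    "  thresholds: %s | default n: %d\n",
    paste(format(x$thresholds), collapse = ", "), x$n_respondents
  ))
  invisible(x)
}

# Presets are frozen populations: loadings are drawn once under a fixed
# internal seed so the same name always denotes the same population.
preset_registry <- function() {
  list(
    sticsa_like = function() {
      loadings <- withr::with_seed(42L, {
        l <- matrix(0, nrow = 22, ncol = 2)
        l[1:11, 1] <- runif(11, 0.80, 0.95)
        l[12:22, 2] <- runif(11, 0.80, 0.95)
        l
      })
      likert_spec(
        loadings = loadings,
        factor_correlation = matrix(c(1, 0.6, 0.6, 1), 2, 2),
        thresholds = c(-1, 0, 1),
        n_respondents = 1622L
      )
    },
    unidim = function() {
      loadings <- withr::with_seed(42L, cbind(runif(10, 0.55, 0.85)))
      likert_spec(
        loadings = loadings,
        thresholds = c(-1, 0, 1),
        n_respondents = 1000L
      )
    }
  )
}

#' Built-in synthetic populations
#'
#' `"sticsa_like"` emulates a 22-item trait-anxiety questionnaire with two
#' correlated factors (11 items each, simple structure, primary loadings drawn
#' uniformly in \[0.80, 0.95\] under a fixed preset seed, factor correlation
#' 0.6) answered on a 4-point Likert scale (thresholds -1, 0, 1). `"unidim"`
#' is a single-factor 10-item scale for unidimensional examples.
#'
#' @param name Preset name, one of `"sticsa_like"` or `"unidim"`.
#' @return A [likert_spec()].
#' @export
#' @examples
#' likert_preset("sticsa_like")
likert_preset <- function(name) {
  registry <- preset_registry()
  if (!is.character(name) || length(name) != 1L || !name %in% names(registry)) {
    abort(sprintf(
      "Unknown preset %s. Registered presets: %s.",
      if (is.character(name) && length(name) == 1L) paste0('"', name, '"') else "value",
      paste0('"', names(registry), '"', collapse = ", ")
    ))
  }
  registry[[name]]()
}

#' Simulate Likert responses from a known factor structure
#'
#' Draws latent factor scores from a zero-mean multivariate normal with the
#' spec's factor correlation, forms each item's latent response as
#' `loadings %*% factors` plus a normal residual scaled so the latent item has
#' unit total variance, and discretizes through the spec's thresholds: the
#' recorded category is the number of thresholds below the latent value, plus
#' one.
#'
#' @param spec A [likert_spec()].
#' @param n Number of respondents (defaults to `spec$n_respondents`).
#' @param seed Integer seed; the same `(spec, n, seed)` always reproduces the
#'   same dataset. `NULL` uses the current RNG stream.
#'
#' @return An object of class `likert_sim`: a list with `responses` (tibble of
#'   integer item responses), `true_scores` (tibble of the generating factor
#'   scores) and `spec`.
#' @export
#' @examples
#' dat <- simulate_likert(likert_preset("unidim"), n = 50, seed = 1)
#' dat$responses[1:3, 1:4]
simulate_likert <- function(spec, n = spec$n_respondents, seed = NULL) {
  if (!inherits(spec, "likert_spec")) {
    abort("`spec` must be a `likert_spec` (see `likert_spec()` or `likert_preset()`).")
  }
  check_scalar_number(n, "n", min = 1)
  n <- as.integer(n)
  lam <- spec$loadings
  phi <- spec$factor_correlation
  communality <- rowSums((lam %*% phi) * lam)
  resid_sd <- sqrt(pmax(1 - communality, 0))

  sim <- with_seed_or_current(seed, {
    z <- matrix(rnorm(n * spec$n_factors), nrow = n)
    f <- z %*% chol(phi) # rows ~ MVN(0, phi)
    latent <- f %*% t(lam) +
      matrix(rnorm(n * spec$n_items), nrow = n) %*% diag(resid_sd, spec$n_items)
    list(f = f, latent = latent)
  })

  responses <- matrix(
    findInterval(sim$latent, spec$thresholds) + 1L,
    nrow = n, dimnames = list(NULL, rownames(lam))
  )
  structure(
    list(
      responses = tibble::as_tibble(responses),
      true_scores = tibble::as_tibble(
        matrix(sim$f, nrow = n, dimnames = list(NULL, colnames(lam)))
      ),
      spec = spec
    ),
    class = "likert_sim"
  )
}

#' @method print likert_sim
#' @export
print.likert_sim <- function(x, ...) {
  cat(sprintf(
    "<likert_sim> %d respondents x %d items (%d categories, %d factor%s)\n",
    nrow(x$responses), x$spec$n_items, x$spec$n_categories,
    x$spec$n_factors, if (x$spec$n_factors > 1) "s" else ""
  ))
  invisible(x)
}
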