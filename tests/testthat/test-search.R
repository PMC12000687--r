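test_that("alpha draws follow a scaled Beta(1,3)", {
  draws <- withr::with_seed(1, draw_alphas(1e5, scale = 8))
  expect_true(all(draws > 0 & draws < 8))
  # Beta(1,3) mean is 1/4
  draws1 <- withr::with_seed(2, draw_alphas(1e5, scale = 1))
  expect_lt(abs(mean(draws1) - 0.25), 0.005)
  # seeded determinism
  expect_identical(
    withr::with_seed(3, draw_alphas(4, scale = 8)),
    withr::with_seed(3, draw_alphas(4, scale = 8))
  )
})

test_that("the selection score balances accuracy against brevity", {
  expect_equal(selection_score(c(0.9, 0.8), 10, 22), 0.8 * 12 / 22)
  expect_equal(selection_score(c(0.99, 0.5), 22, 22), 0)
  expect_equal(selection_score(1.0, 0, 1), 1.0)
  expect_error(selection_score(numeric(0), 1, 2), "at least one")

  # never exceeds the worst dimension; equality only with zero items
  withr::with_seed(4, {
    for (i in 1:25) {
      r2 <- runif(3, -0.2, 1)
      n_inc <- sample(0:10, 1)
      s <- selection_score(r2, n_inc, 10)
      if (min(r2) > 0) expect_lte(s, min(r2))
      if (n_inc == 0) expect_equal(s, min(r2))
      expect_equal(s, min(r2) * (1 - n_inc / 10))
    }
  })
})

make_search_fixture <- function(n = 240, seed = 5) {
  dat <- simulate_likert(likert_preset("unidim"), n = n, seed = seed)
  y <- sum_scores(dat$responses)
  idx <- split_data(n, seed = seed)
  list(
    xt = dat$responses[idx$train, ], yt = y[idx$train, , drop = FALSE],
    xv = dat$responses[idx$validation, ], yv = y[idx$validation, , drop = FALSE]
  )
}

test_that("a near-zero alpha search keeps every item", {
  f <- make_search_fixture()
  fr <- run_search(f$xt, f$yt, f$xv, f$yv, n_iterations = 1, scale = 1e-9, seed = 6)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$n_included, 10L)
  expect_equal(fr$r2_total, 1, tolerance = 1e-9)
})

test_that("the search equals a manual loop over the reducer with the same draws", {
  f <- make_search_fixture()
  fr <- suppressMessages(
    run_search(f$xt, f$yt, f$xv, f$yv, n_iterations = 30, scale = 3, seed = 7)
  )

  manual <- withr::with_seed(7L, {
    lapply(1:30, function(it) {
      alphas <- draw_alphas(1, scale = 3)
      model <- fit_facsimile(f$xt, f$yt, alphas = alphas)
      if (is.null(model)) {
        return(NULL)
      }
      pred <- predict(model, f$xv)
      r2 <- r_squared(f$yv$total, pred$total)
      list(
        iteration = it, alpha = alphas, n_included = length(model$included_items),
        r2 = r2, included = model$included_items,
        score = selection_score(r2, length(model$included_items), 10)
      )
    })
  })
  manual <- manual[!vapply(manual, is.null, logical(1))]
  expect_equal(nrow(fr), length(manual))
  expect_equal(fr$iteration, vapply(manual, `[[`, numeric(1), "iteration"))
  expect_equal(fr$alpha_total, vapply(manual, `[[`, numeric(1), "alpha"))
  expect_equal(fr$n_included, vapply(manual, `[[`, integer(1), "n_included"))
  expect_equal(fr$r2_total, vapply(manual, `[[`, numeric(1), "r2"))
  expect_equal(fr$score, vapply(manual, `[[`, numeric(1), "score"))
  for (i in seq_along(manual)) {
    expect_equal(fr$model[[i]]$included_items, manual[[i]]$included)
  }
})

test_that("searches are reproducible and unidimensional candidates collapse by item count", {
  f <- make_search_fixture()
  fr1 <- suppressMessages(run_search(f$xt, f$yt, f$xv, f$yv, n_iterations = 40, scale = 4, seed = 8))
  fr2 <- suppressMessages(run_search(f$xt, f$yt, f$xv, f$yv, n_iterations = 40, scale = 4, seed = 8))
  expect_equal(tidy(fr1), tidy(fr2))

  # single dimension: equal item counts imply the same item set and R2
  for (k in unique(fr1$n_included)) {
    sub <- fr1[fr1$n_included == k, ]
    sets <- unique(lapply(sub$model, `[[`, "included_items"))
    expect_length(sets, 1)
    expect_equal(diff(range(sub$r2_total)), 0, tolerance = 1e-12)
  }
})

fake_frontier <- function(scores, n_included, iterations = seq_along(scores)) {
  out <- tibble::tibble(
    iteration = iterations,
    alpha_total = 0.5,
    n_included = as.integer(n_included),
    r2_total = scores + (1 - n_included / 22) * 0, # r2 column unused by score ties
    r2_min = scores / (1 - n_included / 22),
    score = scores,
    model = replicate(length(scores), list(dummy = TRUE), simplify = FALSE)
  )
  structure(out,
    class = c("facsimile_frontier", class(out)),
    dimensions = "total", n_items_total = 22L,
    n_iterations = length(scores), n_empty_dropped = 0L, scale = 8
  )
}

test_that("best_model maximizes the score with brevity tie-breaks", {
  single <- fake_frontier(0.4, 5)
  expect_equal(best_model(single)$iteration, 1)

  two <- fake_frontier(c(0.40, 0.45), c(8, 12))
  expect_equal(best_model(two)$score, 0.45)

  tie <- fake_frontier(c(0.45, 0.45), c(12, 8))
  expect_equal(best_model(tie)$n_included, 8L)

  tie2 <- fake_frontier(c(0.45, 0.45), c(8, 8), iterations = c(4, 2))
  expect_equal(best_model(tie2)$iteration, 2)
})

test_that("frontier_curve is the per-count maximum of the worst-dimension R2", {
  f <- make_search_fixture()
  fr <- suppressMessages(run_search(f$xt, f$yt, f$xv, f$yv, n_iterations = 40, scale = 4, seed = 9))
  fc <- frontier_curve(fr)

  # brute-force group-by oracle
  oracle <- vapply(
    fc$n_included,
    function(k) max(fr$r2_min[fr$n_included == k]),
    numeric(1)
  )
  expect_equal(fc$r2, oracle)
  expect_equal(fc$n_included, sort(unique(fr$n_included)))
  expect_equal(sum(fc$n_candidates), nrow(fr))

  # full-item candidates predict sum scores perfectly
  if (10 %in% fc$n_included) {
    expect_equal(fc$r2[fc$n_included == 10], 1, tolerance = 1e-6)
  }
})

test_that("the frontier envelope is non-decreasing for noiseless sum targets", {
  dat <- simulate_likert(likert_preset("unidim"), n = 1200, seed = 10)
  y <- sum_scores(dat$responses)
  idx <- split_data(1200, seed = 10)
  fr <- suppressMessages(run_search(
    dat$responses[idx$train, ], y[idx$train, , drop = FALSE],
    dat$responses[idx$validation, ], y[idx$validation, , drop = FALSE],
    n_iterations = 120, scale = 4, seed = 11
  ))
  fc <- frontier_curve(fr)
  expect_true(all(diff(fc$r2) > -0.01))
})
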