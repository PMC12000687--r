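test_that("lasso selection matches the coordinate-descent oracle on small instances", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      n <- sample(6:12, 1)
      p <- sample(3:5, 1)
      x <- matrix(sample.int(4, n * p, replace = TRUE), n, p)
      colnames(x) <- sprintf("item_%02d", 1:p)
      y <- as.numeric(x %*% runif(p, -1, 2) + rnorm(n, 0, 0.3))
    })
    xs <- standardize_pop(x)
    for (alpha in c(0, 0.01, 0.05, 0.1, 0.25, 0.5, 1, 2)) {
      sel <- select_items_lasso(x, y, alpha)
      oracle <- oracle_cd_lasso(xs, y, alpha)
      expect_equal(unname(sel$coefficients), oracle$beta,
        tolerance = 1e-6,
        label = sprintf("coefficients (seed %d, alpha %.2f)", seed, alpha)
      )
      expect_equal(sel$intercept, oracle$intercept, tolerance = 1e-8)
      expect_setequal(sel$included_items, colnames(x)[oracle$beta != 0])
    }
  }
})

test_that("the closed-form null threshold empties the model", {
  x <- toy_responses(20, 3, seed = 7)
  y <- sum_scores(x)$total
  ub <- unname(alpha_upper_bound(x, y))
  expect_length(select_items_lasso(x, y, ub * 1.0001)$included_items, 0)
  expect_gt(length(select_items_lasso(x, y, ub * 0.99)$included_items), 0)

  # brute force on the same instance: the oracle agrees that nothing survives
  oracle <- oracle_cd_lasso(standardize_pop(as.matrix(x)), y, ub * 1.0001)
  expect_true(all(oracle$beta == 0))
})

test_that("alpha = 0 on a sum-score target reproduces the target exactly", {
  x <- toy_responses(60, 8, seed = 9)
  y <- sum_scores(x)$total
  sel <- select_items_lasso(x, y, alpha = 0)
  expect_setequal(sel$included_items, names(x))
  xs <- standardize_pop(as.matrix(x))
  fitted <- as.numeric(xs %*% sel$coefficients) + sel$intercept
  expect_equal(fitted, y, tolerance = 1e-8)
  expect_equal(sel$training_r2, 1, tolerance = 1e-10)
})

test_that("zero-variance items are excluded with a warning", {
  x <- toy_responses(30, 4, seed = 10)
  x$item_02 <- 2 # floor-effect item
  y <- sum_scores(x)$total
  expect_warning(sel <- select_items_lasso(x, y, alpha = 0.01), "item_02")
  expect_equal(unname(sel$coefficients["item_02"]), 0)
  expect_false("item_02" %in% sel$included_items)
})

test_that("union_included pools selections in original item order", {
  x <- toy_responses(40, 6, seed = 11)
  y <- tibble::tibble(
    a = as.numeric(as.matrix(x) %*% c(1, 0, 2, 0, 0, 0)),
    b = as.numeric(as.matrix(x) %*% c(0, 0, 1, 0, 3, 0))
  )
  s1 <- select_items_lasso(x, y$a, alpha = 0.3, dimension = "a")
  s2 <- select_items_lasso(x, y$b, alpha = 0.3, dimension = "b")
  expect_setequal(s1$included_items, c("item_01", "item_03"))
  expect_setequal(s2$included_items, c("item_03", "item_05"))
  expect_equal(union_included(list(s1, s2)), c("item_01", "item_03", "item_05"))
  # single dimension passes through unchanged
  expect_equal(union_included(list(s1)), s1$included_items)
  expect_equal(union_included(s1), s1$included_items)
  # empty union
  ub <- max(alpha_upper_bound(x, y)) * 1.01
  s_empty <- select_items_lasso(x, y$a, alpha = ub)
  expect_length(union_included(list(s_empty, s_empty)), 0)
})

test_that("refitting the full item set on sum scores recovers unit weights", {
  x <- toy_responses(80, 22, seed = 12)
  y <- sum_scores(x)
  m <- refit_union(x, y, included = names(x))
  expect_equal(unname(m$weights[, 1]), rep(1, 22), tolerance = 1e-8)
  expect_equal(unname(m$intercepts), 0, tolerance = 1e-7)
  pred <- predict(m, x)
  expect_equal(pred$total, y$total, tolerance = 1e-8)
})

test_that("refit matches the normal-equations oracle and duplicates dimensions independently", {
  x <- toy_responses(25, 3, seed = 13)
  y <- tibble::tibble(t = 2 * x$item_01 - 0.5 * x$item_03 + 1)
  m <- refit_union(x, y, included = c("item_01", "item_03"))
  expect_equal(unname(m$weights[, 1]), c(2, -0.5), tolerance = 1e-8)
  expect_equal(unname(m$intercepts), 1, tolerance = 1e-8)

  a <- cbind(1, as.matrix(x[, c("item_01", "item_03")]))
  oracle <- solve(crossprod(a), crossprod(a, y$t))
  expect_equal(unname(c(m$intercepts, m$weights[, 1])), as.vector(oracle), tolerance = 1e-8)

  y2 <- tibble::tibble(t = y$t, t_copy = y$t)
  m2 <- refit_union(x, y2, included = c("item_01", "item_03"))
  expect_equal(m2$weights[, "t"], m2$weights[, "t_copy"])

  expect_error(refit_union(x, y, included = character(0)), "alpha")
})

test_that("refit training R2 dominates the step-1 selection R2 per dimension", {
  for (seed in 1:10) {
    dat <- toy_responses(40, 8, seed = 100 + seed)
    y <- withr::with_seed(200 + seed, {
      w <- matrix(runif(16, -1, 1), 8, 2)
      ym <- as.matrix(dat) %*% w + rnorm(80, 0, 1)
      colnames(ym) <- c("d1", "d2")
      tibble::as_tibble(ym)
    })
    alphas <- withr::with_seed(300 + seed, runif(2, 0, 0.8))
    m <- fit_facsimile(dat, y, alphas = alphas)
    if (is.null(m)) next
    for (j in 1:2) {
      expect_gte(m$training_r2[j], m$selections[[j]]$training_r2 - 1e-10)
    }
  }
})

test_that("predictions follow the weighted-sum model and ignore excluded items", {
  m <- structure(
    list(
      included_items = c("item_01", "item_02"),
      weights = matrix(c(2, -1), 2, 1, dimnames = list(c("item_01", "item_02"), "total")),
      intercepts = c(total = 0.5),
      training_r2 = c(total = 1),
      alphas_used = NULL,
      n_items_total = 4L,
      item_names = sprintf("item_%02d", 1:4)
    ),
    class = "item_model"
  )
  newdata <- tibble::tibble(item_01 = 3, item_02 = 4)
  expect_equal(predict(m, newdata)$total, 2 * 3 - 1 * 4 + 0.5)

  # sparsity consistency: excluded columns with arbitrary values change nothing
  extra <- tibble::tibble(item_01 = 3, item_02 = 4, item_03 = 99, item_04 = -7)
  expect_equal(predict(m, extra), predict(m, newdata))

  expect_error(predict(m, tibble::tibble(item_01 = 3)), "item_02")

  # zero weights -> intercept everywhere
  m$weights[] <- 0
  expect_equal(predict(m, extra)$total, 0.5)
})

test_that("an exact sparse linear target is recovered as noise vanishes", {
  x <- toy_responses(120, 6, seed = 15)
  true_w <- c(1.5, 0, 0, -2, 0, 0.75)
  signal <- as.numeric(as.matrix(x) %*% true_w)
  for (sd_noise in c(0.2, 0.02)) {
    y <- signal + withr::with_seed(16, rnorm(120, 0, sd_noise))
    sel <- select_items_lasso(x, y, alpha = 0.05)
    expect_true(all(c("item_01", "item_04", "item_06") %in% sel$included_items))
  }
  # at negligible noise the refit on the true support recovers the weights
  y <- signal + withr::with_seed(17, rnorm(120, 0, 1e-6))
  m <- refit_union(x, y, included = c("item_01", "item_04", "item_06"))
  expect_equal(unname(m$weights[, 1]), c(1.5, -2, 0.75), tolerance = 1e-4)
})

test_that("fit_k_items finds the exact-k model on the deterministic path", {
  dat <- simulate_likert(likert_preset("unidim"), n = 400, seed = 18)
  y <- sum_scores(dat$responses)
  for (k in c(2, 5, 8)) {
    m <- fit_k_items(dat$responses, y, k = k)
    expect_length(m$included_items, k)
    # the recorded alpha reproduces the same selection
    sel <- select_items_lasso(dat$responses, y$total, alpha = m$alphas_used[[1]])
    expect_setequal(sel$included_items, m$included_items)
  }
  expect_error(fit_k_items(dat$responses, y, k = 10), "smaller")
})
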