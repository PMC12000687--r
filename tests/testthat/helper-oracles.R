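# Independent oracles and small data builders used across the suite.

# From-scratch cyclic coordinate descent for the Lasso objective
# (1/2n) * ||y - b0 - X w||^2 + alpha * ||w||_1, unpenalized intercept.
# Deliberately naive (no warm starts, no screening) so it is an independent
# check on the packaged solver.
oracle_cd_lasso <- function(x, y, alpha, tol = 1e-12, maxit = 2e5) {
  n <- nrow(x)
  p <- ncol(x)
  msq <- colMeans(x^2)
  b <- numeric(p)
  b0 <- mean(y)
  r <- y - b0
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      old <- b[j]
      rho <- sum(x[, j] * (r + x[, j] * old)) / n
      b[j] <- sign(rho) * max(abs(rho) - alpha, 0) / msq[j]
      if (b[j] != old) {
        r <- r - x[, j] * (b[j] - old)
        delta <- max(delta, abs(b[j] - old))
      }
    }
    if (delta < tol) break
  }
  list(beta = b, intercept = b0)
}

# z-score columns with the population SD, matching the packaged solver's
# internal standardization.
standardize_pop <- function(x) {
  mu <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2, mu)^2))
  sweep(sweep(x, 2, mu), 2, sds, "/")
}

# Random integer Likert responses with no factor structure.
toy_responses <- function(n, p, categories = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(sample.int(categories, n * p, replace = TRUE), n, p)
    colnames(m) <- sprintf("item_%02d", seq_len(p))
    tibble::as_tibble(m)
  })
}

sticsa_assignment <- function(items) {
  stats::setNames(rep(c("cognitive", "somatic"), each = 11), items)
}

# Monte-Carlo oracle for the Pearson correlation between two Likert items:
# discretizes a closed-form bivariate normal with latent correlation rho
# through the thresholds. Independent of the generator's sampling scheme.
oracle_discretized_cor <- function(rho, thresholds, n_mc = 1e5, seed = 99) {
  withr::with_seed(seed, {
    z1 <- rnorm(n_mc)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_mc)
    c1 <- findInterval(z1, thresholds) + 1
    c2 <- findInterval(z2, thresholds) + 1
    stats::cor(c1, c2)
  })
}

# Align an estimated loading/score column set with a reference one: match
# columns by maximal absolute congruence and flip signs to agree.
align_columns <- function(est, ref) {
  k <- ncol(ref)
  cong <- abs(stats::cor(est, ref))
  perm <- integer(k)
  for (j in seq_len(k)) {
    perm[j] <- which.max(cong[, j])
    cong[perm[j], ] <- -Inf
  }
  out <- est[, perm, drop = FALSE]
  for (j in seq_len(k)) {
    if (stats::cor(out[, j], ref[, j]) < 0) out[, j] <- -out[, j]
  }
  out
}
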