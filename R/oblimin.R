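# Oblique oblimin (quartimin) rotation by gradient projection.
#
# Minimizes the quartimin criterion f(L) = sum_i sum_{j != k} L_ij^2 L_ik^2 / 4
# over oblique rotations of an unrotated loading matrix, following the
# gradient-projection scheme of Bernaards & Jennrich. Deterministic: starts
# from the identity rotation with a backtracking step size.

quartimin_vgq <- function(l) {
  l2 <- l^2
  k <- ncol(l)
  n <- matrix(1, k, k) - diag(k)
  list(
    f = sum(l2 * (l2 %*% n)) / 4,
    gq = l * (l2 %*% n)
  )
}

rotate_oblimin <- function(a, eps = 1e-7, maxit = 1000L) {
  k <- ncol(a)
  tmat <- diag(k)
  al <- 1
  ti <- solve(tmat)
  l <- a %*% t(ti)
  vg <- quartimin_vgq(l)
  f <- vg$f
  g <- -t(t(l) %*% vg$gq %*% ti)
  s <- Inf
  for (iter in seq_len(maxit)) {
    gp <- g - tmat %*% diag(colSums(tmat * g), k)
    s <- sqrt(sum(gp^2))
    if (s < eps) break
    al <- 2 * al
    tt <- tmat
    vgt <- vg
    for (i in 0:20) {
      x <- tmat - al * gp
      tt <- x %*% diag(1 / sqrt(colSums(x^2)), k)
      lt <- a %*% t(solve(tt))
      vgt <- quartimin_vgq(lt)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    tmat <- tt
    l <- a %*% t(solve(tmat))
    vg <- vgt
    f <- vg$f
    g <- -t(t(l) %*% vg$gq %*% solve(tmat))
  }
  phi <- t(tmat) %*% tmat

  # Canonical form: flip factors so the dominant loadings are positive and
  # order by explained sum of squares, so repeated fits are comparable.
  signs <- ifelse(colSums(l^3) < 0, -1, 1)
  l <- l %*% diag(signs, k)
  phi <- diag(signs, k) %*% phi %*% diag(signs, k)
  ord <- order(colSums(l^2), decreasing = TRUE)
  l <- l[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]

  list(loadings = l, phi = phi, criterion = f, converged = s < eps)
}
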