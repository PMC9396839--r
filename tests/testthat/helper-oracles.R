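# Independent brute-force oracles: direct summation formulas written as
# explicit loops, sharing no code with the package internals.

oracle_r2 <- function(e, p) {
  n <- length(e)
  me <- sum(e) / n; mp <- sum(p) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (e[i] - me) * (p[i] - mp)
    sxx <- sxx + (e[i] - me)^2
    syy <- syy + (p[i] - mp)^2
  }
  sxy^2 / (sxx * syy)
}

oracle_slopes <- function(e, p) {
  sep <- 0; spp <- 0; see <- 0
  for (i in seq_along(e)) {
    sep <- sep + e[i] * p[i]
    spp <- spp + p[i]^2
    see <- see + e[i]^2
  }
  c(k = sep / spp, k_prime = sep / see)
}

# solves the through-origin slope by numeric minimization of the residual
# sum of squares, then applies the determination-coefficient formula
oracle_r0_forward <- function(e, p) {
  rss <- function(b) sum((e - b * p)^2)
  k <- optimize(rss, c(-100, 100), tol = 1e-12)$minimum
  ss_tot <- 0
  me <- sum(e) / length(e)
  for (i in seq_along(e)) ss_tot <- ss_tot + (e[i] - me)^2
  1 - rss(k) / ss_tot
}

oracle_r0_uncentered <- function(e, p) {
  num <- 0; see <- 0; spp <- 0
  for (i in seq_along(e)) {
    num <- num + e[i] * p[i]
    see <- see + e[i]^2
    spp <- spp + p[i]^2
  }
  num^2 / (see * spp)
}

oracle_ccc <- function(e, p) {
  n <- length(e)
  me <- sum(e) / n; mp <- sum(p) / n
  num <- 0; se <- 0; sp <- 0
  for (i in seq_len(n)) {
    num <- num + (e[i] - me) * (p[i] - mp)
    se <- se + (e[i] - me)^2
    sp <- sp + (p[i] - mp)^2
  }
  2 * num / (se + sp + n * (me - mp)^2)
}

# exhaustive two-sample permutation test on the difference of means
oracle_perm_pvalue <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- abs(mean(x) - mean(y))
  splits <- combn(length(pooled), n1)
  cnt <- 0
  for (j in seq_len(ncol(splits))) {
    a <- pooled[splits[, j]]
    b <- pooled[-splits[, j]]
    if (abs(mean(a) - mean(b)) >= obs - 1e-12) cnt <- cnt + 1
  }
  cnt / ncol(splits)
}

random_pairs <- function(n, rho = 0.8) {
  e <- runif(n, -2, 8)
  p <- rho * e + (1 - rho) * mean(e) + rnorm(n, 0, 0.5)
  activity_pairs(e, p)
}
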