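# Independent oracles: each recomputes a statistic from first principles,
# sharing no code with the package implementation.

# One-way ANOVA F via explicit sums of squares.
oracle_anova_F <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  k <- length(unique(groups))
  N <- length(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(unlist(tapply(values, groups, function(v) (v - mean(v))^2)))
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  list(F = msb / msw, df1 = k - 1, df2 = N - k,
       p = pf(msb / msw, k - 1, N - k, lower.tail = FALSE))
}

# Pearson chi-square via brute-force expected counts.
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  X2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(X2 = X2, df = df, p = pchisq(X2, df, lower.tail = FALSE))
}

# Average ranks by hand, then the Pearson product-moment formula by sums.
oracle_spearman_rho <- function(x, y) {
  avg_rank <- function(v) {
    sapply(seq_along(v), function(i) {
      sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    })
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# ANCOVA group F via normal equations on hand-built full/reduced designs.
oracle_ancova_F <- function(y, group, age, sex) {
  g <- factor(group)
  G <- sapply(levels(g)[-1], function(l) as.numeric(g == l))
  sexm <- as.numeric(sex == unique(sex)[2])
  Xf <- cbind(1, G, age, sexm)
  Xr <- cbind(1, age, sexm)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  rss_f <- rss(Xf); rss_r <- rss(Xr)
  df1 <- nlevels(g) - 1
  df2 <- length(y) - ncol(Xf)
  Fv <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = pf(Fv, df1, df2, lower.tail = FALSE))
}

# Independent tensor fit: stats::lm with a formula-built design on the
# b-value/direction products, sharing nothing with design_matrix().
oracle_lm_tensor <- function(signals, gtab) {
  g <- gtab$bvecs; b <- gtab$bvals
  df <- data.frame(
    y = log(signals),
    bx2 = b * g[, 1]^2, by2 = b * g[, 2]^2, bz2 = b * g[, 3]^2,
    bxy = 2 * b * g[, 1] * g[, 2], bxz = 2 * b * g[, 1] * g[, 3],
    byz = 2 * b * g[, 2] * g[, 3])
  fit <- lm(y ~ bx2 + by2 + bz2 + bxy + bxz + byz, data = df)
  co <- coef(fit)
  c(dxx = -unname(co["bx2"]), dyy = -unname(co["by2"]),
    dzz = -unname(co["bz2"]), dxy = -unname(co["bxy"]),
    dxz = -unname(co["bxz"]), dyz = -unname(co["byz"]),
    s0 = exp(unname(co["(Intercept)"])))
}

# Closed-form single-tensor DWI signal (forward model used as fit oracle).
oracle_signal <- function(d6, gtab, s0) {
  D <- matrix(c(d6[1], d6[4], d6[5],
                d6[4], d6[2], d6[6],
                d6[5], d6[6], d6[3]), 3, 3)
  sapply(seq_along(gtab$bvals), function(i) {
    g <- gtab$bvecs[i, ]
    s0 * exp(-gtab$bvals[i] * drop(t(g) %*% D %*% g))
  })
}

random_spd_tensor <- function(scale = 1e-3) {
  A <- matrix(rnorm(9, sd = scale), 3, 3)
  M <- A %*% t(A) / 3 + diag(3) * 0.2 * scale
  c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

rotate_tensor <- function(d6, R) {
  M <- matrix(c(d6[1], d6[4], d6[5],
                d6[4], d6[2], d6[6],
                d6[5], d6[6], d6[3]), 3, 3)
  M2 <- R %*% M %*% t(R)
  c(M2[1, 1], M2[2, 2], M2[3, 3], M2[1, 2], M2[1, 3], M2[2, 3])
}
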