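# Independent brute-force oracles, kept deliberately naive and separate
# from the package's implementations.

# GLCM by explicit double loop over pixels
naive_glcm <- function(patch, levels, offset, symmetric = TRUE) {
  P <- matrix(0, levels, levels)
  dr <- offset[1]; dc <- offset[2]
  for (r in seq_len(nrow(patch))) {
    for (c in seq_len(ncol(patch))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nrow(patch) && c2 >= 1 && c2 <= ncol(patch)) {
        i <- patch[r, c] + 1; j <- patch[r2, c2] + 1
        P[i, j] <- P[i, j] + 1
        if (symmetric) P[j, i] <- P[j, i] + 1
      }
    }
  }
  P / sum(P)
}

# the eight statistics by explicit double loop over matrix cells
naive_texture_stats <- function(P) {
  N <- nrow(P)
  mu_i <- mu_j <- 0
  for (i in 0:(N - 1)) for (j in 0:(N - 1)) {
    mu_i <- mu_i + i * P[i + 1, j + 1]
    mu_j <- mu_j + j * P[i + 1, j + 1]
  }
  m <- v <- hom <- con <- dis <- ent <- sm <- 0
  var_i <- var_j <- cv <- 0
  for (i in 0:(N - 1)) for (j in 0:(N - 1)) {
    p <- P[i + 1, j + 1]
    m <- m + i * p
    hom <- hom + p / (1 + (i - j)^2)
    con <- con + (i - j)^2 * p
    dis <- dis + abs(i - j) * p
    if (p > 0) ent <- ent - p * log(p)
    sm <- sm + p^2
    var_i <- var_i + (i - mu_i)^2 * p
    var_j <- var_j + (j - mu_j)^2 * p
    cv <- cv + (i - mu_i) * (j - mu_j) * p
  }
  for (i in 0:(N - 1)) for (j in 0:(N - 1))
    v <- v + (i - m)^2 * P[i + 1, j + 1]
  corr <- if (var_i <= 0 || var_j <= 0) 1 else cv / sqrt(var_i * var_j)
  c(mean = m, var = v, hom = hom, con = con, dis = dis, ent = ent,
    sm = sm, corr = corr)
}

# textbook two-pass one-way ANOVA F
two_pass_anova_f <- function(values, groups) {
  g <- factor(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (lev in levels(g)) {
    x <- values[g == lev]
    ssb <- ssb + length(x) * (mean(x) - grand)^2
    ssw <- ssw + sum((x - mean(x))^2)
  }
  k <- nlevels(g); n <- length(values)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# 2-norm condition number of a column subset
cond_number <- function(X) {
  sv <- svd(X, nu = 0, nv = 0)$d
  sv <- sv[sv > 0]
  max(sv) / min(sv)
}
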