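# Feature sensitivity screening (one-way ANOVA F against damage level)
# and successive-projections-algorithm (SPA) extraction of a
# low-collinearity sensitive subset.

#' Upper-tail critical value of the F distribution
#'
#' Used for the sensitivity thresholds. Note the screening convention
#' followed here quotes the critical value at `(k, n)` degrees of freedom
#' (number of classes, number of trees) — `f_critical(0.01, 4, 840)` is
#' 3.34 and `f_critical(1e-10, 4, 840)` is 13.57 — while [anova_f()]
#' itself uses the classical `k - 1` numerator degrees of freedom for the
#' statistic and its p-value. Both are documented so either convention
#' can be applied knowingly.
#'
#' @param alpha_tail Upper-tail probability in (0, 1).
#' @param df1,df2 Degrees of freedom.
#' @return The F quantile with upper-tail mass `alpha_tail`.
#' @examples
#' round(f_critical(0.01, 4, 840), 2)   # 3.34
#' round(f_critical(1e-10, 4, 840), 2)  # 13.57
#' @export
f_critical <- function(alpha_tail, df1, df2) {
  if (!is.finite(alpha_tail) || alpha_tail <= 0 || alpha_tail >= 1)
    stop("alpha_tail must be in (0, 1)")
  if (!is.finite(df1) || !is.finite(df2) || df1 <= 0 || df2 <= 0)
    stop("degrees of freedom must be positive and finite")
  stats::qf(alpha_tail, df1, df2, lower.tail = FALSE)
}

#' One-way ANOVA F of a feature against damage level
#'
#' Classical between/within mean-square ratio with `df1 = k - 1`,
#' `df2 = n - k`, fitted through [stats::lm()]/[stats::anova()]. Groups
#' that are perfectly separated (zero within-group variance, positive
#' between-group variance) yield the `F = Inf` sentinel and are flagged
#' sensitive. Sensitivity flags compare F with [f_critical()] at the
#' screening convention's `(k, n)` degrees of freedom.
#'
#' @param values Numeric feature values, one per tree.
#' @param levels Integer damage level per tree.
#' @param alpha Screening tail for the `sensitive` flag (default 0.01).
#' @param alpha_high Tail for the `highly_sensitive` flag (default 1e-10).
#' @return List with `F`, `p`, `df1`, `df2`, `sensitive`,
#'   `highly_sensitive`.
#' @export
anova_f <- function(values, levels, alpha = 0.01, alpha_high = 1e-10) {
  g <- factor(levels)
  n <- length(values)
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups")
  if (any(table(g) < 2))
    stop("every group needs at least 2 observations")
  ssw <- sum(tapply(values, g, function(x) sum((x - mean(x))^2)))
  sst <- sum((values - mean(values))^2)
  if (ssw <= 1e-12 * max(sst, 1)) {
    # degenerate separation (or all-constant data)
    Fv <- if (sst > ssw) Inf else 0
    p <- if (is.infinite(Fv)) 0 else 1
  } else {
    tab <- stats::anova(stats::lm(values ~ g))
    Fv <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
  }
  crit <- f_critical(alpha, k, n)
  crit_high <- f_critical(alpha_high, k, n)
  list(F = Fv, p = p, df1 = k - 1L, df2 = n - k,
       sensitive = Fv > crit, highly_sensitive = Fv > crit_high)
}

#' ANOVA sensitivity screening of a feature table
#'
#' Applies [anova_f()] to every feature column.
#'
#' @param table A [feature_table()].
#' @param levels Integer damage level per tree.
#' @inheritParams anova_f
#' @return A `data.frame` with one row per feature: `feature`, `F`, `p`,
#'   `sensitive`, `highly_sensitive`.
#' @export
screen_features <- function(table, levels, alpha = 0.01,
                            alpha_high = 1e-10) {
  res <- lapply(colnames(table$values), function(nm)
    anova_f(table$values[, nm], levels, alpha, alpha_high))
  data.frame(feature = colnames(table$values),
             F = vapply(res, `[[`, 0, "F"),
             p = vapply(res, `[[`, 0, "p"),
             sensitive = vapply(res, `[[`, TRUE, "sensitive"),
             highly_sensitive = vapply(res, `[[`, TRUE,
                                       "highly_sensitive"),
             row.names = NULL)
}

# nearest-class-centroid classifier on standardised features: the cheap,
# deterministic evaluation model scoring candidate SPA subsets
.centroid_fit <- function(X, y) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
  cls <- sort(unique(y))
  centroids <- do.call(rbind, lapply(cls, function(cl)
    colMeans(Xs[y == cl, , drop = FALSE])))
  list(mu = mu, sd = sd, classes = cls, centroids = centroids)
}

.centroid_predict <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$mu), 2, fit$sd, "/")
  d2 <- outer(rowSums(Xs^2), rowSums(fit$centroids^2), "+") -
    2 * Xs %*% t(fit$centroids)
  fit$classes[max.col(-d2, ties.method = "first")]
}

#' Successive projections algorithm feature selection
#'
#' Forward selection that minimises collinearity: starting from each
#' candidate feature, repeatedly project every unselected column onto the
#' orthogonal complement of the span of the selected ones and append the
#' column with maximal residual norm. Each chain prefix of size
#' `k_min..k_max` is scored by validation misclassification of a
#' nearest-class-centroid classifier; the subset with minimal validation
#' error wins (ties broken towards smaller subsets, then lexicographic
#' feature order).
#'
#' @param X Numeric trees x features matrix (normalised), named columns.
#' @param y Integer damage level per tree.
#' @param k_min,k_max Smallest/largest subset size to consider.
#' @param validation_fraction Fraction of rows held out (stratified) for
#'   subset scoring.
#' @param seed Seed for the calibration/validation split.
#' @return An object of class `spa_selection`: list with `selected`
#'   (feature names, in selection order), `k`, `error` (validation
#'   misclassification of the winner), `chains` (per start feature:
#'   members and residual projection norms) and `scores` (all evaluated
#'   subsets).
#' @export
spa_select <- function(X, y, k_min = 3, k_max = NULL,
                       validation_fraction = 0.25, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have named columns")
  if (anyNA(X)) stop("X must not contain missing values")
  p <- ncol(X)
  if (is.null(k_max)) k_max <- min(p, 15)
  stopifnot(k_min >= 1, k_max >= k_min)
  if (k_max > p) stop("k_max exceeds the number of features")

  plan <- make_split(seq_len(nrow(X)), y,
                     train_fraction = 1 - validation_fraction,
                     seed = seed)
  cal <- plan$train; val <- plan$test
  Xc <- X[cal, , drop = FALSE]

  tol <- 1e-10
  chains <- vector("list", p)
  names(chains) <- colnames(X)
  max_len <- 0L
  for (s in seq_len(p)) {
    resid <- Xc
    members <- s
    norms <- numeric(0)  # max residual norm at each projection step
    for (step in seq_len(k_max - 1)) {
      z <- resid[, members[length(members)]]
      zz <- sum(z^2)
      if (zz < tol^2) break
      # project all columns onto the orthogonal complement of z
      coef <- colSums(resid * z) / zz
      resid <- resid - outer(z, coef)
      cand_norm <- sqrt(colSums(resid^2))
      cand_norm[members] <- -Inf
      best <- which.max(cand_norm)
      if (cand_norm[best] < tol) break
      members <- c(members, best)
      norms <- c(norms, cand_norm[best])
    }
    chains[[s]] <- list(start = colnames(X)[s],
                        members = colnames(X)[members], norms = norms)
    max_len <- max(max_len, length(members))
  }
  if (max_len < k_min)
    stop("rank-deficient X: longest attainable chain has ", max_len,
         " features, k_min = ", k_min)

  scores <- list()
  for (s in seq_len(p)) {
    mem <- match(chains[[s]]$members, colnames(X))
    for (k in seq(k_min, min(k_max, length(mem)))) {
      sub <- mem[seq_len(k)]
      fit <- .centroid_fit(Xc[, sub, drop = FALSE], y[cal])
      pred <- .centroid_predict(fit, X[val, sub, drop = FALSE])
      scores[[length(scores) + 1]] <- list(
        start = colnames(X)[s], k = k,
        features = colnames(X)[sub],
        error = mean(pred != y[val]))
    }
  }
  err <- vapply(scores, `[[`, 0, "error")
  ks <- vapply(scores, `[[`, 0L, "k")
  key <- vapply(scores, function(sc)
    paste(sort(sc$features), collapse = "\r"), "")
  ord <- order(err, ks, key)
  winner <- scores[[ord[1]]]
  structure(list(selected = winner$features, k = winner$k,
                 error = winner$error, chains = chains,
                 scores = data.frame(
                   start = vapply(scores, `[[`, "", "start"),
                   k = ks, error = err,
                   features = vapply(scores, function(sc)
                     paste(sc$features, collapse = ";"), ""),
                   row.names = NULL)),
            class = "spa_selection")
}

#' @export
print.spa_selection <- function(x, ...) {
  cat(sprintf("<spa_selection> %d feature(s), validation error %.4f\n",
              x$k, x$error))
  cat(paste(" ", x$selected, collapse = "\n"), "\n")
  invisible(x)
}

#' Screen by ANOVA, then select by SPA
#'
#' The screening-selection composition used by the pipeline: features not
#' sensitive at `alpha` are dropped, then [spa_select()] runs on the
#' sensitive ones.
#'
#' @param table A normalised [feature_table()].
#' @param levels Integer damage level per tree.
#' @inheritParams spa_select
#' @inheritParams anova_f
#' @return List with `screening` (the [screen_features()] table) and
#'   `selection` (the [spa_select()] result).
#' @export
select_sensitive <- function(table, levels, k_min = 3, k_max = NULL,
                             alpha = 0.01, validation_fraction = 0.25,
                             seed = 1L) {
  scr <- screen_features(table, levels, alpha = alpha)
  keep <- scr$feature[scr$sensitive]
  if (length(keep) < k_min)
    stop("only ", length(keep), " sensitive feature(s), k_min = ", k_min)
  sel <- spa_select(table$values[, keep, drop = FALSE], levels,
                    k_min = k_min,
                    k_max = if (is.null(k_max)) min(length(keep), 15)
                            else min(k_max, length(keep)),
                    validation_fraction = validation_fraction, seed = seed)
  list(screening = scr, selection = sel)
}
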