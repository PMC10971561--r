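#' Feature table container
#'
#' A trees-by-features value matrix with namespaced feature names
#' (`RGB_VI:*`, `MS_VI:*`, `RGB_TF:*`) and an explicit normalisation
#' state. Min-max bounds are stored on normalisation so the identical
#' scaling can be replayed on held-out data.
#'
#' @param values Numeric matrix, one row per tree, named columns.
#' @param tree_id Tree identifiers (default: rownames of `values`).
#' @param normalised Logical flag.
#' @param bounds Optional 2-row matrix (`min`, `max`) per feature.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, tree_id = rownames(values),
                          normalised = FALSE, bounds = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("features must be named")
  if (anyDuplicated(colnames(values))) stop("feature names must be unique")
  if (is.null(tree_id)) tree_id <- as.character(seq_len(nrow(values)))
  if (anyNA(values)) stop("feature table contains missing values")
  rownames(values) <- as.character(tree_id)
  structure(list(values = values, tree_id = as.character(tree_id),
                 normalised = normalised, bounds = bounds),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d trees x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalised) "normalised" else "raw"))
  ns <- sub(":.*$", "", colnames(x$values))
  for (s in unique(ns))
    cat(sprintf("  %s: %d features\n", s, sum(ns == s)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Column-bind feature tables
#'
#' @param ... `feature_table`s over the same trees and with the same
#'   normalisation state.
#' @return A combined `feature_table`.
#' @export
cbind_features <- function(...) {
  tabs <- list(...)
  ids <- tabs[[1]]$tree_id
  norm <- tabs[[1]]$normalised
  for (t in tabs[-1]) {
    if (!identical(t$tree_id, ids)) stop("tree ids differ between tables")
    if (!identical(t$normalised, norm)) stop("normalisation states differ")
  }
  vals <- do.call(cbind, lapply(tabs, `[[`, "values"))
  bounds <- if (all(vapply(tabs, function(t) !is.null(t$bounds), TRUE)))
    do.call(cbind, lapply(tabs, `[[`, "bounds"))
  feature_table(vals, ids, normalised = norm, bounds = bounds)
}

#' Select a namespace or named subset of features
#'
#' @param table A `feature_table`.
#' @param set Namespace prefix (`"RGB_VI"`, `"MS_VI"`, `"RGB_TF"`, or the
#'   combined `"RGB_VI&TF"`), or `NULL` with explicit `features`.
#' @param features Optional exact (namespaced) feature names.
#' @return The subset `feature_table`.
#' @export
select_features <- function(table, set = NULL, features = NULL) {
  nm <- colnames(table$values)
  if (!is.null(features)) {
    missing <- setdiff(features, nm)
    if (length(missing))
      stop("unknown feature(s): ", paste(missing, collapse = ", "))
    keep <- features
  } else if (!is.null(set)) {
    prefixes <- switch(set,
      "RGB_VI&TF" = c("RGB_VI", "RGB_TF"),
      set)
    keep <- nm[sub(":.*$", "", nm) %in% prefixes]
    if (!length(keep)) stop("no features in set ", set)
  } else stop("give either `set` or `features`")
  feature_table(table$values[, keep, drop = FALSE], table$tree_id,
                normalised = table$normalised,
                bounds = table$bounds[, keep, drop = FALSE])
}

#' Min-max normalise a feature table
#'
#' Scales each feature to \[0, 1\] by its observed (or supplied) minimum
#' and maximum. Constant features map to 0. The bounds are stored on the
#' result so held-out data can be scaled identically.
#'
#' @param table A raw `feature_table`.
#' @param bounds Optional 2-row (`min`, `max`) matrix from a previous
#'   normalisation; default derives bounds from `table` itself.
#' @return The normalised `feature_table`.
#' @examples
#' ft <- feature_table(cbind(`RGB_VI:x` = c(2, 4, 6)))
#' normalise_features(ft)$values[, 1]  # 0.0 0.5 1.0
#' @export
normalise_features <- function(table, bounds = NULL) {
  if (table$normalised) stop("table is already normalised")
  v <- table$values
  if (is.null(bounds)) {
    bounds <- rbind(min = apply(v, 2, min), max = apply(v, 2, max))
    colnames(bounds) <- colnames(v)
  } else {
    if (!all(colnames(v) %in% colnames(bounds)))
      stop("bounds lack some features")
    bounds <- bounds[, colnames(v), drop = FALSE]
  }
  rng <- bounds["max", ] - bounds["min", ]
  scaled <- sweep(v, 2, bounds["min", ], "-")
  nz <- rng > 0
  scaled[, nz] <- sweep(scaled[, nz, drop = FALSE], 2, rng[nz], "/")
  scaled[, !nz] <- 0
  feature_table(scaled, table$tree_id, normalised = TRUE, bounds = bounds)
}

#' Read / write a feature table as CSV
#'
#' One row per tree: `tree_id` followed by one column per namespaced
#' feature.
#'
#' @param table A `feature_table`.
#' @param path File path.
#' @return `read_features` returns the `feature_table`; `write_features`
#'   returns `path` invisibly. Normalisation state is not persisted.
#' @export
write_features <- function(table, path) {
  df <- data.frame(tree_id = table$tree_id, check.names = FALSE)
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  feature_table(vals, tree_id = df$tree_id)
}
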