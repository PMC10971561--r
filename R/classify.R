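# Damage-level classifiers (random forest, small 1-D CNN) and the
# sample-size sweep.

# deterministic largest-remainder allocation of `target` draws over the
# class counts in `tab` (ties resolved in class order)
.allocate <- function(tab, target) {
  exact <- tab * target / sum(tab)
  base <- floor(exact)
  rem <- target - sum(base)
  if (rem > 0) {
    ord <- order(-(exact - base), seq_along(tab))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Stratified train/test split
#'
#' Partitions ids into a training share (default 75%) and a test share
#' (default 25%), stratified by class so every level keeps its share
#' within one tree of the overall fraction. Deterministic per seed.
#'
#' @param ids Identifiers.
#' @param labels Class label per id.
#' @param train_fraction Training share.
#' @param stratified Stratify by class (default) or split completely at
#'   random.
#' @param seed Integer seed.
#' @return Object of class `split_plan`: list with `train`, `test`,
#'   `stratified`, `seed`.
#' @export
make_split <- function(ids, labels, train_fraction = 0.75,
                       stratified = TRUE, seed = 1L) {
  stopifnot(length(ids) == length(labels),
            train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  if (stratified) {
    tab <- table(labels)
    if (any(tab < 4))
      stop("stratification error: every class needs >= 4 members")
    n_train <- .allocate(tab, round(train_fraction * length(ids)))
    train <- unlist(lapply(seq_along(tab), function(ci) {
      members <- which(labels == names(tab)[ci])
      members[sample.int(length(members), n_train[ci])]
    }), use.names = FALSE)
  } else {
    train <- sample.int(length(ids), round(train_fraction * length(ids)))
  }
  structure(list(train = ids[sort(train)],
                 test = ids[sort(setdiff(seq_along(ids), train))],
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_plan")
}

#' Model specification
#'
#' @param kind `"RF"` or `"CNN"`.
#' @param ... Hyperparameter overrides. RF: `ntree` (500), `mtry`
#'   (sqrt of feature count). CNN: `filters` (16), `kernel` (3), `pool`
#'   (2), `dense` (32), `epochs` (200), `lr` (1e-3), `batch` (32).
#' @param seed Training seed.
#' @return A `model_spec` list.
#' @export
model_spec <- function(kind = c("RF", "CNN"), ..., seed = 1L) {
  kind <- match.arg(kind)
  defaults <- if (kind == "RF") list(ntree = 500, mtry = NULL)
  else list(filters = 16, kernel = 3, pool = 2, dense = 32,
            epochs = 200, lr = 1e-3, batch = 32)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", kind, ": ",
         paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  num <- unlist(defaults[!vapply(defaults, is.null, TRUE)])
  if (any(num <= 0)) stop("hyperparameters must be positive")
  structure(list(kind = kind, hyper = defaults, seed = as.integer(seed)),
            class = "model_spec")
}

#' Train a damage-level classifier
#'
#' `train_rf` fits a bagged decision-tree ensemble (majority vote) and
#' reports Gini importances normalised to sum 1; `train_cnn` fits the
#' [cnn_fit()] network with mean-absolute-input-gradient importances.
#' `train_model` dispatches on `spec$kind`.
#'
#' @param table A normalised [feature_table()].
#' @param labels Integer damage level per tree (aligned with the table).
#' @param plan A [make_split()] plan over the table's tree ids; only
#'   `plan$train` rows are used for fitting.
#' @param spec A [model_spec()].
#' @return Object of class `damage_model`: the fitted model, `kind`,
#'   `features` and `importances`.
#' @export
train_model <- function(table, labels, plan, spec) {
  switch(spec$kind,
         RF = train_rf(table, labels, plan, spec),
         CNN = train_cnn(table, labels, plan, spec))
}

#' @rdname train_model
#' @export
train_rf <- function(table, labels, plan, spec = model_spec("RF")) {
  stopifnot(spec$kind == "RF")
  idx <- match(plan$train, table$tree_id)
  X <- table$values[idx, , drop = FALSE]
  y <- labels[idx]
  if (length(unique(y)) < 2) stop("single-class training data")
  mtry <- spec$hyper$mtry
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(X))))
  set.seed(spec$seed)
  fit <- randomForest::randomForest(
    x = as.data.frame(X, check.names = TRUE), y = factor(y),
    ntree = spec$hyper$ntree, mtry = mtry, importance = FALSE)
  imp <- fit$importance[, "MeanDecreaseGini"]
  imp <- imp / sum(imp)
  names(imp) <- colnames(X)
  structure(list(kind = "RF", fit = fit, features = colnames(X),
                 importances = imp, spec = spec),
            class = "damage_model")
}

#' @rdname train_model
#' @export
train_cnn <- function(table, labels, plan, spec = model_spec("CNN")) {
  stopifnot(spec$kind == "CNN")
  idx <- match(plan$train, table$tree_id)
  X <- table$values[idx, , drop = FALSE]
  y <- labels[idx]
  if (length(unique(y)) < 2) stop("single-class training data")
  h <- spec$hyper
  fit <- cnn_fit(X, y, filters = h$filters, kernel = h$kernel,
                 pool = h$pool, dense = h$dense, epochs = h$epochs,
                 lr = h$lr, batch = h$batch, seed = spec$seed)
  structure(list(kind = "CNN", fit = fit, features = colnames(X),
                 importances = fit$importances, spec = spec),
            class = "damage_model")
}

#' Predict damage levels
#'
#' @param object A [train_model()] fit.
#' @param table A `feature_table` carrying the model's features.
#' @param ... Unused.
#' @return Integer damage levels, named by tree id.
#' @export
predict.damage_model <- function(object, table, ...) {
  X <- table$values[, object$features, drop = FALSE]
  out <- if (object$kind == "RF")
    as.integer(as.character(predict(
      object$fit, as.data.frame(X, check.names = TRUE))))
  else as.integer(predict(object$fit, X))
  names(out) <- table$tree_id
  out
}

#' Train on the split's training share and evaluate on its test share
#'
#' @inheritParams train_model
#' @param meta Extra metadata stored on the report.
#' @return An [evaluation_report()].
#' @export
evaluate_split <- function(table, labels, plan, spec, meta = list()) {
  model <- train_model(table, labels, plan, spec)
  test_idx <- match(plan$test, table$tree_id)
  test_tab <- feature_table(table$values[test_idx, , drop = FALSE],
                            table$tree_id[test_idx],
                            normalised = table$normalised)
  pred <- predict(model, test_tab)
  evaluation_report(pred, labels[test_idx],
                    labels = sort(unique(labels)),
                    importances = model$importances,
                    meta = c(meta, list(model = spec$kind,
                                        n = length(labels))))
}

#' Sample-size sweep
#'
#' For each requested sample size, draws a stratified subsample, splits
#' it 75/25, trains every model on every feature table and evaluates on
#' the held-out share; repeated over seeds.
#'
#' @param tables Named list of normalised [feature_table()]s (one per
#'   feature set), or a single table.
#' @param labels Integer damage level per tree.
#' @param sizes Sample sizes (default 140 to 840 by 100).
#' @param specs List of [model_spec()]s (default one RF, one CNN).
#' @param seeds Integer seeds; each seed redraws subsample and split.
#' @param train_fraction,stratified Passed to [make_split()].
#' @return `data.frame` with one row per (size, feature_set, model, seed):
#'   `OA` and `Kappa` on the test share. Sizes below the stratification
#'   minimum are skipped with a warning.
#' @export
sample_size_sweep <- function(tables, labels,
                              sizes = seq(140, 840, by = 100),
                              specs = list(model_spec("RF"),
                                           model_spec("CNN")),
                              seeds = 1L, train_fraction = 0.75,
                              stratified = TRUE) {
  if (inherits(tables, "feature_table")) tables <- list(features = tables)
  if (is.null(names(tables))) stop("tables must be named by feature set")
  n <- length(labels)
  if (max(sizes) > n) stop("max size exceeds available trees")
  tab <- table(labels)
  rows <- list()
  for (size in sizes) {
    alloc <- .allocate(tab, size)
    if (any(alloc < 4 / train_fraction)) {
      warning("size ", size, " below stratification minimum; skipped")
      next
    }
    for (seed in seeds) {
      set.seed(seed + 7 * size)
      sub <- unlist(lapply(seq_along(tab), function(ci) {
        members <- which(labels == names(tab)[ci])
        if (size == n) members
        else members[sample.int(length(members), alloc[ci])]
      }), use.names = FALSE)
      plan <- make_split(sub, labels[sub],
                         train_fraction = train_fraction,
                         stratified = stratified, seed = seed + 13)
      for (fs in names(tables)) {
        ft <- tables[[fs]]
        sub_tab <- feature_table(ft$values[sub, , drop = FALSE],
                                 ft$tree_id[sub],
                                 normalised = ft$normalised)
        sub_plan <- structure(list(
          train = ft$tree_id[plan$train], test = ft$tree_id[plan$test],
          stratified = stratified, seed = plan$seed),
          class = "split_plan")
        for (spec in specs) {
          spec$seed <- as.integer(seed)
          rep <- evaluate_split(sub_tab, labels[sub], sub_plan, spec,
                                meta = list(size = size,
                                            feature_set = fs,
                                            seed = seed))
          rows[[length(rows) + 1]] <- data.frame(
            size = size, feature_set = fs, model = spec$kind,
            seed = seed, OA = rep$OA, Kappa = rep$Kappa)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a sweep over seeds
#'
#' @param sweep Result of [sample_size_sweep()].
#' @return `data.frame` keyed by (size, feature_set, model) with mean and
#'   sd of OA and Kappa over seeds.
#' @export
summarise_sweep <- function(sweep) {
  agg <- stats::aggregate(cbind(OA, Kappa) ~ size + feature_set + model,
                          sweep, function(x) c(mean = mean(x),
                                               sd = stats::sd(x)))
  data.frame(size = agg$size, feature_set = agg$feature_set,
             model = agg$model,
             OA_mean = agg$OA[, "mean"], OA_sd = agg$OA[, "sd"],
             Kappa_mean = agg$Kappa[, "mean"],
             Kappa_sd = agg$Kappa[, "sd"])
}
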