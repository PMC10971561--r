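test_that("stratified splits hit the 75/25 shares and are deterministic", {
  ids <- sprintf("t%03d", 1:840)
  labels <- rep(1:4, each = 210)
  plan <- make_split(ids, labels, seed = 5)
  expect_equal(length(plan$train), 630)
  expect_equal(length(plan$test), 210)
  expect_length(intersect(plan$train, plan$test), 0)
  expect_setequal(c(plan$train, plan$test), ids)
  # per-class test share within one tree of 25%
  test_by_class <- table(labels[match(plan$test, ids)])
  expect_true(all(abs(test_by_class - 0.25 * 210) <= 1))
  expect_identical(make_split(ids, labels, seed = 5), plan)
  expect_false(identical(make_split(ids, labels, seed = 6)$train,
                         plan$train))
  expect_error(make_split(1:9, c(1, 1, 1, 2, 2, 2, 3, 3, 3), seed = 1),
               "stratification")
})

make_sep_table <- function(n = 40, seed = 1) {
  # two features, four linearly separable classes
  set.seed(seed)
  y <- rep(1:4, each = n / 4)
  X <- cbind(f1 = y %% 2 + rnorm(n, 0, 0.05),
             f2 = y %/% 3 + rnorm(n, 0, 0.05))
  colnames(X) <- c("RGB_VI:f1", "RGB_VI:f2")
  list(table = feature_table(X, sprintf("t%02d", 1:n), normalised = TRUE),
       labels = y)
}

test_that("random forest separates separable classes and normalises importances", {
  d <- make_sep_table()
  plan <- make_split(d$table$tree_id, d$labels, seed = 2)
  model <- train_rf(d$table, d$labels, plan, model_spec("RF", seed = 2))
  expect_equal(sum(model$importances), 1)
  expect_true(all(model$importances >= 0))
  pred_train <- predict(model, d$table)[plan$train]
  expect_equal(mean(pred_train == d$labels[match(plan$train,
                                                 d$table$tree_id)]), 1)
  expect_error(train_rf(d$table, rep(1, 40), plan), "single-class")
})

test_that("pure-noise features rank below informative ones in RF importance", {
  wins <- vapply(1:10, function(seed) {
    set.seed(seed)
    y <- rep(1:4, each = 20)
    X <- cbind(signal = y + rnorm(80, 0, 0.3), noise = rnorm(80))
    colnames(X) <- c("RGB_VI:signal", "RGB_VI:noise")
    tab <- feature_table(X, sprintf("t%02d", 1:80), normalised = TRUE)
    plan <- make_split(tab$tree_id, y, seed = seed)
    m <- train_rf(tab, y, plan, model_spec("RF", ntree = 200, seed = seed))
    m$importances["RGB_VI:signal"] > m$importances["RGB_VI:noise"]
  }, TRUE)
  expect_true(all(wins))
})

test_that("the CNN is deterministic per seed, fits separable data, and outputs proper softmax", {
  d <- make_sep_table(n = 80, seed = 3)
  plan <- make_split(d$table$tree_id, d$labels, seed = 3)
  spec <- model_spec("CNN", epochs = 60, seed = 3)
  m1 <- train_cnn(d$table, d$labels, plan, spec)
  m2 <- train_cnn(d$table, d$labels, plan, spec)
  expect_identical(predict(m1, d$table), predict(m2, d$table))
  expect_equal(sum(m1$importances), 1)

  # training accuracy on separable classes
  train_idx <- match(plan$train, d$table$tree_id)
  pred <- predict(m1, d$table)[plan$train]
  expect_gte(mean(pred == d$labels[train_idx]), 0.95)

  probs <- predict(m1$fit, d$table$values, type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)),
               tolerance = 1e-9)
  expect_true(all(probs >= 0))
})

test_that("CNN handles few features and rejects degenerate input", {
  set.seed(4)
  y <- rep(1:2, each = 20)
  X <- cbind(a = y + rnorm(40, 0, 0.1), b = rnorm(40))
  expect_s3_class(cnn_fit(X, y, epochs = 5, seed = 1), "cnn_model")
  expect_error(cnn_fit(X[, 1, drop = FALSE], y, epochs = 5), "2 features")
  expect_error(cnn_fit(X, rep(1, 40), epochs = 5), "single class")
})

test_that("the sample-size sweep covers the full grid and reuses all trees at full size", {
  set.seed(9)
  n <- 120
  y <- rep(1:4, each = 30)
  X <- cbind(`RGB_VI:a` = y + rnorm(n, 0, 0.3),
             `RGB_VI:b` = rnorm(n))
  tabs <- list(RGB_VI = feature_table(X, sprintf("t%03d", 1:n),
                                      normalised = TRUE))
  sizes <- c(40, 80, 120)
  specs <- list(model_spec("RF", ntree = 50),
                model_spec("CNN", epochs = 5))
  sw <- sample_size_sweep(tabs, y, sizes = sizes, specs = specs,
                          seeds = 1:2)
  expect_equal(nrow(sw), length(sizes) * 1 * 2 * 2)
  expect_setequal(unique(sw$size), sizes)
  expect_setequal(unique(sw$model), c("RF", "CNN"))
  expect_true(all(sw$OA >= 0 & sw$OA <= 1))
  # aggregation keys every (size, set, model) cell exactly once
  agg <- summarise_sweep(sw)
  expect_equal(nrow(agg), length(sizes) * 2)
  # a size below the stratification minimum is skipped with a warning
  expect_warning(sample_size_sweep(tabs, y, sizes = c(12, 40),
                                   specs = specs[1], seeds = 1),
                 "skipped")
  expect_error(sample_size_sweep(tabs, y, sizes = 200, specs = specs[1]),
               "exceeds")
})

test_that("sweep determinism: same seeds give identical accuracy rows", {
  set.seed(10)
  y <- rep(1:4, each = 20)
  X <- cbind(`RGB_VI:a` = y + rnorm(80, 0, 0.3),
             `RGB_VI:b` = rnorm(80))
  tabs <- list(RGB_VI = feature_table(X, sprintf("t%03d", 1:80),
                                      normalised = TRUE))
  s1 <- sample_size_sweep(tabs, y, sizes = c(40, 80),
                          specs = list(model_spec("RF", ntree = 50)),
                          seeds = 7)
  s2 <- sample_size_sweep(tabs, y, sizes = c(40, 80),
                          specs = list(model_spec("RF", ntree = 50)),
                          seeds = 7)
  expect_identical(s1, s2)
})
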