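# A cheap network configuration for fast optimizer checks.
small_cfg <- function(epochs = 25, seed = 1) {
  net_config(input_size = 16, stem_channels = 6, stem_pools = 2, blocks = 2,
             layers_per_block = 2, growth = 4, epochs = epochs,
             batch_size = 16, lr = 3e-3, train_seed = seed)
}

# Flat-gray images whose intensity encodes the label: trivially decodable.
gray_images <- function(labels, size = 16) {
  lapply(labels, function(l) matrix(l / 120, size, size))
}

test_that("the split is by drug pair with no leakage and is deterministic", {
  records <- data.frame(pair_id = rep(c(1:8, 0), each = 10))
  s1 <- split_dataset(records, split_spec(split_seed = 3))
  s2 <- split_dataset(records, split_spec(split_seed = 3))
  expect_identical(s1$split, s2$split)
  # every pair lands wholly in the pool or wholly in test
  tab <- table(s1$pair_id, s1$split %in% c("train", "val"))
  expect_true(all(rowSums(tab > 0) == 1))
  pool_pairs <- unique(s1$pair_id[s1$split %in% c("train", "val")])
  expect_length(setdiff(pool_pairs, 0), 4)
  # empty-well references (pair 0) always join the training pool
  expect_true(all(s1$split[s1$pair_id == 0] %in% c("train", "val")))
  # explicit pair list is honoured
  s3 <- split_dataset(records, split_spec(train_pairs = c(1, 2, 3)))
  expect_setequal(unique(s3$pair_id[s3$split == "test"]), 4:8)
  # requesting unknown pairs fails
  expect_error(split_dataset(records, split_spec(train_pairs = 99)),
               "not present")
})

test_that("validation fraction 0 gives an empty validation set", {
  records <- data.frame(pair_id = rep(1:4, each = 5))
  s <- split_dataset(records, split_spec(val_fraction = 0))
  expect_equal(sum(s$split == "val"), 0)
})

test_that("training converges to a constant target and improves over epochs", {
  set.seed(42)
  labels <- rep(50, 40)
  imgs <- lapply(1:40, function(i) matrix(runif(256, 0.3, 0.7), 16))
  m <- train_viability_model(imgs, labels, imgs[1:10], labels[1:10],
                             cfg = small_cfg())
  pred <- predict_viability(m, imgs[1:10])
  expect_lt(max(abs(pred - 50)), 10)
  # learnable signal: intensity-coded labels, retained val MSE improves
  set.seed(43)
  labs <- runif(60, 0, 100)
  imgs2 <- gray_images(labs)
  m2 <- train_viability_model(imgs2[1:45], labs[1:45], imgs2[46:60],
                              labs[46:60], cfg = small_cfg())
  expect_lt(min(m2$history$val_mse), m2$history$val_mse[1])
  expect_error(train_viability_model(list(), numeric(0), cfg = small_cfg()),
               "empty")
})

test_that("training is deterministic given the seed", {
  set.seed(7)
  labs <- runif(30, 0, 100)
  imgs <- gray_images(labs)
  m1 <- train_viability_model(imgs, labs, cfg = small_cfg(epochs = 3, seed = 9))
  m2 <- train_viability_model(imgs, labs, cfg = small_cfg(epochs = 3, seed = 9))
  expect_identical(m1$history, m2$history)
  expect_identical(predict_viability(m1, imgs[1:5]),
                   predict_viability(m2, imgs[1:5]))
})

test_that("prediction handles empty input, duplicates and shape mismatch", {
  set.seed(8)
  labs <- runif(20, 0, 100)
  imgs <- gray_images(labs)
  m <- train_viability_model(imgs, labs, cfg = small_cfg(epochs = 2))
  expect_identical(predict_viability(m, list()), numeric(0))
  p <- predict_viability(m, list(imgs[[1]], imgs[[1]], imgs[[2]]))
  expect_equal(p[1], p[2])
  expect_true(all(is.finite(p)))
  expect_error(predict_viability(m, list(matrix(0, 8, 8))), "must be 16 x 16")
})

test_that("per-day normalization anchors the untreated well at 100", {
  preds <- data.frame(
    plate_id = "p1", day = 8, row = c(0, 1, 2), col = c(0, 0, 1),
    raw_pred = c(80, 40, 100))
  norm <- normalize_per_day(preds)
  expect_equal(norm$viability, c(100, 50, 125))
  # negatives floor at 0
  preds$raw_pred <- c(80, -10, 20)
  expect_equal(normalize_per_day(preds)$viability, c(100, 0, 25))
  # missing or non-positive reference flags the whole plate-day group
  preds2 <- data.frame(
    plate_id = rep(c("a", "b"), each = 2), day = 8,
    row = c(0, 1, 1, 2), col = c(0, 0, 0, 0),
    raw_pred = c(-5, 40, 50, 60))
  norm2 <- normalize_per_day(preds2)
  expect_true(all(norm2$flag[norm2$plate_id == "a"] == "missing_reference"))
  expect_true(all(is.na(norm2$viability[norm2$plate_id == "a"])))
  expect_true(all(norm2$flag[norm2$plate_id == "b"] == "missing_reference"))
})

test_that("agreement statistics match the closed-form OLS oracle", {
  # perfect agreement (the stock summary warns about the perfect fit)
  fit_perfect <- suppressWarnings(evaluate_predictions(1:10, 1:10))
  expect_equal(fit_perfect$adj_r_squared, 1)
  # hand-computed 4-point oracle: pred (1,2,3,4), obs (1,2,3,5)
  # slope = 6.5/5, SSE = 0.30, SST = 8.75
  fm <- evaluate_predictions(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(fm$slope, 1.3)
  expect_equal(fm$intercept, -0.5)
  expect_equal(fm$r_squared, 169 / 175)
  expect_equal(fm$adj_r_squared, 166 / 175)
  # cross-check against the stock linear-model summary
  sm <- summary(lm(c(1, 2, 3, 5) ~ c(1, 2, 3, 4)))
  expect_equal(fm$adj_r_squared, sm$adj.r.squared)
  expect_equal(fm$p_value, sm$coefficients[2, 4])
  # independent noise: adjusted R^2 near zero
  set.seed(21)
  fm0 <- evaluate_predictions(rnorm(400), rnorm(400))
  expect_lt(abs(fm0$adj_r_squared), 0.05)
  # degenerate inputs
  expect_error(evaluate_predictions(rep(1, 5), 1:5), "zero variance")
  expect_error(evaluate_predictions(1:2, 1:2), "at least 3")
})
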