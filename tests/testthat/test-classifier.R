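test_that("a separable rule is learned exactly and matches the rule oracle", {
  df <- toy_waterbodies(200)
  cfg <- classifier_config(max_iterations = 300, random_seed = 7)
  m <- train_risk_model(df[, FEATURE_COLS], df$larvae_present, cfg)
  pred <- predict_risk(m, df[, FEATURE_COLS])
  fv <- field_validation(pred$label, df$larvae_present)
  expect_equal(fv$recall, 1)
  expect_equal(fv$precision, 1)
  expect_equal(pred$label, as.integer(df$visual_turbidity == "very turbid"))
})

test_that("labels follow the decision threshold row by row and monotonically", {
  df <- toy_waterbodies(150, seed = 3)
  cfg <- classifier_config(max_iterations = 100, random_seed = 1)
  m <- train_risk_model(df[, FEATURE_COLS], df$larvae_present, cfg)
  pred <- predict_risk(m, df[, FEATURE_COLS])
  expect_equal(pred$label, as.integer(pred$probability >= 0.5))

  thresholds <- c(1e-9, 0.25, 0.5, 0.75, 1)
  highs <- vapply(thresholds, function(t) {
    sum(predict_risk(m, df[, FEATURE_COLS], threshold = t)$label)
  }, numeric(1))
  expect_true(all(diff(highs) <= 0)) # raising the cut never adds high calls
  expect_equal(highs[1], nrow(df))   # threshold near 0: everything high
  expect_equal(highs[length(highs)], 0) # threshold 1: nothing certain
})

test_that("training is deterministic and rejects degenerate inputs", {
  df <- toy_waterbodies(120, seed = 5)
  cfg <- classifier_config(max_iterations = 80, random_seed = 42)
  m1 <- train_risk_model(df[, FEATURE_COLS], df$larvae_present, cfg)
  m2 <- train_risk_model(df[, FEATURE_COLS], df$larvae_present, cfg)
  expect_identical(predict_risk(m1, df[, FEATURE_COLS])$probability,
                   predict_risk(m2, df[, FEATURE_COLS])$probability)

  expect_error(train_risk_model(df[, FEATURE_COLS],
                                rep(1L, nrow(df)), cfg), "both classes")
  expect_error(train_risk_model(df[, FEATURE_COLS],
                                df$larvae_present[-1], cfg), "length")

  new <- df[1:3, FEATURE_COLS]
  new$visual_turbidity <- "opaque"
  expect_error(predict_risk(m1, new), "opaque")
})

test_that("identical duplicated rows with consistent labels are reproduced", {
  base <- toy_waterbodies(40, seed = 8)
  df <- base[rep(seq_len(nrow(base)), each = 3), ]
  cfg <- classifier_config(max_iterations = 200, random_seed = 2)
  m <- train_risk_model(df[, FEATURE_COLS], df$larvae_present, cfg)
  pred <- predict_risk(m, df[, FEATURE_COLS])
  expect_equal(pred$label, df$larvae_present)
})

test_that("stratified folds balance size and class ratio", {
  y <- c(rep(1L, 37), rep(0L, 83))
  fold <- lsmeval:::stratified_folds(y, 5, seed = 13)
  sizes <- table(fold)
  expect_true(max(sizes) - min(sizes) <= 1)
  pos <- tapply(y, fold, sum)
  expect_true(max(pos) - min(pos) <= 1)
  expect_error(lsmeval:::stratified_folds(c(1L, rep(0L, 20)), 5, 1),
               "fewer than")
})

test_that("cross-validation is perfect on separable data and null on noise", {
  df <- toy_waterbodies(250, seed = 14)
  cfg <- classifier_config(max_iterations = 150, random_seed = 4)
  cv <- cross_validate_risk(df[, FEATURE_COLS], df$larvae_present, cfg)
  expect_equal(cv$recall, 1)
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(cv$accuracy, mean(cv$per_fold$accuracy))

  # permutation null: with labels shuffled, held-out accuracy approaches
  # the empirical base rate (majority class share)
  wb <- gen_waterbodies(generator_config(n_waterbodies = 800,
                                         random_seed = 17))$waterbodies
  set.seed(17)
  ynull <- sample(wb$larvae_present)
  cvn <- cross_validate_risk(wb[, FEATURE_COLS], ynull,
                             classifier_config(max_iterations = 150,
                                               random_seed = 17))
  base_rate <- max(mean(ynull), 1 - mean(ynull))
  expect_lt(abs(cvn$accuracy - base_rate), 0.05)
})

test_that("feature importance is normalized and finds the informative feature", {
  df <- toy_waterbodies(300, seed = 21)
  cfg <- classifier_config(max_iterations = 200, random_seed = 6)
  m <- train_risk_model(df[, FEATURE_COLS], df$larvae_present, cfg)
  rfi <- feature_importance(m)
  expect_equal(sum(rfi), 100, tolerance = 1e-9)
  expect_true(all(rfi >= 0))
  expect_setequal(names(rfi), FEATURE_COLS)
  expect_gt(rfi[["visual_turbidity"]], 90)
})

test_that("generator-ranked weights surface as the top importance pair", {
  wb <- gen_waterbodies(generator_config(n_waterbodies = 3000,
                                         random_seed = 23))$waterbodies
  cfg <- classifier_config(max_iterations = 300, random_seed = 23)
  m <- train_risk_model(wb[, FEATURE_COLS], wb$larvae_present, cfg)
  rfi <- sort(feature_importance(m), decreasing = TRUE)
  expect_setequal(names(rfi)[1:2], c("waterbody_type", "visual_turbidity"))
})

test_that("field validation counts agree with an element-wise loop", {
  fv <- field_validation(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(fv$accuracy, 1)

  # degenerate always-high classifier: recall 1, precision = prevalence
  y <- c(rep(1L, 3), rep(0L, 7))
  fv2 <- field_validation(rep(1L, 10), y)
  expect_equal(fv2$recall, 1)
  expect_equal(fv2$precision, 0.3)

  set.seed(31)
  for (i in 1:10) {
    p <- sample(0:1, 25, TRUE)
    y <- sample(0:1, 25, TRUE)
    fv <- field_validation(p, y)
    tp <- fp <- fn <- tn <- 0
    for (j in seq_along(p)) {
      if (p[j] == 1 && y[j] == 1) tp <- tp + 1
      if (p[j] == 1 && y[j] == 0) fp <- fp + 1
      if (p[j] == 0 && y[j] == 1) fn <- fn + 1
      if (p[j] == 0 && y[j] == 0) tn <- tn + 1
    }
    expect_equal(c(fv$tp, fv$fp, fv$fn, fv$tn), c(tp, fp, fn, tn))
  }
  expect_error(field_validation(c(1, 0), c(1, 0, 1)), "length")
})
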