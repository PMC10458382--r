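test_that("stratified splitting hits the 70:30 arithmetic exactly", {
  tab <- make_separable_table(n_per_class = 50, seed = 1)
  tab$label <- rep(c(0L, 1L), c(70, 30))        # 30 positives of 100 rows
  parts <- split_data(tab, split_spec(0.30, seed = 4))
  expect_identical(nrow(parts$train), 70L)
  expect_identical(nrow(parts$test), 30L)
  expect_identical(sum(parts$train$label), 21L)
  expect_identical(sum(parts$test$label), 9L)
  parts2 <- split_data(tab, split_spec(0.30, seed = 4))
  expect_identical(parts, parts2)
  one_class <- tab; one_class$label <- 0L
  expect_error(split_data(one_class), "single-class")
})

test_that("train and test partitions are disjoint and exhaustive", {
  tab <- make_separable_table(n_per_class = 40, seed = 2)
  tab$row_id <- seq_len(nrow(tab))
  parts <- split_data(tab, split_spec(0.25, seed = 9))
  expect_length(intersect(parts$train$row_id, parts$test$row_id), 0)
  expect_setequal(c(parts$train$row_id, parts$test$row_id), tab$row_id)
})

test_that("accuracy score is correct fraction with strict input checks", {
  expect_equal(accuracy_score(c(1, 1, 0, 1, 0, 0, 1, 1, 0, 0),
                              c(1, 1, 0, 1, 0, 0, 1, 1, 0, 1)), 0.9)
  expect_equal(accuracy_score(1:0, 1:0), 1)
  expect_equal(accuracy_score(c(1, 1), c(0, 0)), 0)
  expect_error(accuracy_score(c(1), c(1, 0)), "differ in length")
  expect_error(accuracy_score(integer(0), integer(0)), "empty")
})

test_that("position decoding honors bounds, scales and the subsample map", {
  sp <- hyperparam_space_xgb()
  lb_t <- ifelse(sp$log_mask, log10(sp$lb), sp$lb)
  ub_t <- ifelse(sp$log_mask, log10(sp$ub), sp$ub)

  lo <- decode_position(lb_t, sp)
  expect_equal(lo$learning_rate, 1.5e-15)
  expect_equal(lo$max_depth, 1)
  expect_equal(lo$gamma, 1e-9)
  expect_equal(lo$alpha, 1e-6)
  expect_equal(lo$subsample, 0.005)            # 1/200 clamped to floor

  hi <- decode_position(ub_t, sp)
  expect_equal(hi$learning_rate, 0.9)
  expect_equal(hi$max_depth, 200)
  expect_equal(hi$subsample, 1)                # 200/200

  mid <- decode_position((lb_t + ub_t) / 2, sp)
  expect_true(mid$learning_rate >= 1.5e-15 && mid$learning_rate <= 0.9)
  expect_true(mid$colsample_bytree >= 0.001 && mid$colsample_bytree <= 1)
  expect_true(mid$max_depth == round(mid$max_depth))
  expect_true(mid$min_child_weight == round(mid$min_child_weight))
  expect_true(mid$subsample > 0 && mid$subsample <= 1)

  raw <- decode_position(ub_t, sp, subsample_as_printed = TRUE)
  expect_equal(raw$subsample, 200)
  expect_error(decode_position(ub_t + 1, sp), "outside")
})

test_that("the tuning objective is one minus accuracy and deterministic", {
  tab <- make_separable_table(n_per_class = 60, seed = 3, gap = 4)
  sp <- hyperparam_space_xgb()
  # a mid-box position with a sane learning rate
  pos <- ifelse(sp$log_mask, log10(sp$lb), sp$lb)
  pos <- (pos + ifelse(sp$log_mask, log10(sp$ub), sp$ub)) / 2
  pos[1] <- log10(0.3)
  obj1 <- tune_objective(pos, tab, sp, split_spec(0.2, seed = 7))
  obj2 <- tune_objective(pos, tab, sp, split_spec(0.2, seed = 7))
  expect_identical(obj1, obj2)
  expect_true(obj1 >= 0 && obj1 <= 1)
  # reconstruct the accuracy by hand: objective + accuracy = 1
  hp <- decode_position(pos, sp)
  parts <- split_data(tab, split_spec(0.2, seed = 7))
  model <- fit_final(parts$train, hp, seed = 7)
  acc <- accuracy_score(predict_labels(model, parts$test), parts$test$label)
  expect_equal(obj1 + acc, 1)
})

test_that("tuning improves on the untuned default for separable data", {
  tab <- make_separable_table(n_per_class = 60, seed = 5, gap = 1)
  parts <- split_data(tab, split_spec(0.3, seed = 5))
  rep <- tune_xgb(parts$train,
                  aocfg = ao_config(pop_size = 8, max_iter = 8, seed = 5),
                  inner_split = split_spec(0.2, seed = 5))
  expect_true(all(diff(rep$trace) <= 0))
  expect_true(rep$best_objective >= 0 && rep$best_objective <= 1)
  inner <- split_data(parts$train, split_spec(0.2, seed = 5))
  untuned <- baseline_fit(inner$train, "untuned", seed = 5)
  untuned_obj <- 1 - accuracy_score(predict_labels(untuned, inner$test),
                                    inner$test$label)
  expect_lte(rep$best_objective, untuned_obj + 1e-9)
  rep2 <- tune_xgb(parts$train,
                   aocfg = ao_config(pop_size = 8, max_iter = 8, seed = 5),
                   inner_split = split_spec(0.2, seed = 5))
  expect_identical(rep$best_hyperparams, rep2$best_hyperparams)
  expect_identical(rep$trace, rep2$trace)
})

test_that("every baseline kind trains and beats the majority class on train", {
  tab <- make_separable_table(n_per_class = 100, seed = 6, gap = 2)
  for (kind in c("DT", "RF", "GBC", "untuned")) {
    m <- baseline_fit(tab, kind, seed = 2)
    acc <- accuracy_score(predict_labels(m, tab), tab$label)
    expect_gte(acc, max(mean(tab$label == 1), mean(tab$label == 0)))
    s <- predict_scores(m, tab)
    expect_true(all(s >= 0 & s <= 1))
  }
})
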