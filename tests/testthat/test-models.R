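# Architecture arithmetic, metric identities, baseline configuration,
# search-space sampling and training mechanics.

test_that("architecture shapes follow the halving rule (independent recount)", {
  set.seed(31)
  for (rep in 1:25) {
    nb <- sample(2:4, 1)
    arch <- cnn_architecture(sample(c(16L, 48L, 80L, 112L, 144L), nb, TRUE),
                             sample(c(3L, 6L, 9L, 12L), nb, TRUE),
                             sample(seq(64L, 512L, 64L), 1))
    sh <- architecture_shapes(arch)
    # independent recomputation: repeated floor-halving from 692
    L <- 692L
    for (i in seq_len(nb)) {
      expect_equal(sh$conv_lengths[i], L)
      L <- as.integer(floor(L / 2))
      expect_equal(sh$pooled_lengths[i], L)
    }
    expect_equal(sh$flatten, L * arch$conv_filters[nb])
  }
  # two blocks: 692 -> 346 -> 173
  expect_equal(architecture_shapes(
    cnn_architecture(c(16L, 16L), c(3L, 3L), 64L))$pooled_lengths, c(346L, 173L))
})

test_that("the tuned stage architectures have the published geometry", {
  for (mk in list(stage1_architecture, stage2_architecture)) {
    sh <- architecture_shapes(mk())
    expect_equal(sh$conv_lengths, c(692L, 346L, 173L))
    expect_equal(sh$pooled_lengths, c(346L, 173L, 86L))
    expect_equal(sh$flatten, 9632L)
  }
  expect_equal(stage1_architecture()$dense_units, 192L)
  expect_equal(stage2_architecture()$dense_units, 448L)
  # forward pass agrees with the declared flatten size
  fit <- init_cnn_fit(stage1_architecture())
  expect_equal(nrow(fit$params$W1), 9632L)
  expect_length(predict(fit, matrix(rnorm(692), 1), type = "logit"), 1)
})

test_that("out-of-vocabulary hyperparameters error in strict mode only", {
  expect_error(cnn_architecture(c(20L, 16L), c(3L, 3L), 64L), "vocabulary")
  expect_warning(a <- cnn_architecture(c(20L, 16L), c(3L, 3L), 64L,
                                       strict = FALSE), "vocabulary")
  expect_equal(a$conv_filters[1], 20L)
  expect_error(cnn_architecture(16L, 3L, 64L))          # too few blocks
  expect_error(train_config(learning_rate = 0.5), "1e-2")
})

test_that("confusion-matrix metrics match direct arithmetic and identities", {
  # confusion TP=8 TN=5 FP=1 FN=2 via constructed probabilities
  p <- c(rep(.9, 8), rep(.1, 2), rep(.2, 5), .8)
  y <- c(rep(1, 10), rep(0, 6))
  m <- evaluate_metrics(p, y)
  expect_equal(m$accuracy, 13 / 16)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  # perfect predictions
  mp <- evaluate_metrics(c(.9, .9, .1), c(1, 1, 0))
  expect_true(all(unlist(mp[c("accuracy", "sensitivity", "specificity",
                              "precision", "f1")]) == 1))
  # all-positive predictor on balanced data
  ma <- evaluate_metrics(rep(1, 10), rep(c(0, 1), 5))
  expect_equal(ma$sensitivity, 1)
  expect_equal(ma$specificity, 0)
  # label flip swaps sensitivity and specificity
  mf <- evaluate_metrics(1 - p, 1 - y)
  expect_equal(mf$sensitivity, m$specificity)
  expect_equal(mf$specificity, m$sensitivity)
  # F1 ignores true negatives
  m2 <- evaluate_metrics(c(p, rep(.1, 50)), c(y, rep(0, 50)))
  expect_equal(m2$f1, m$f1)
  # single-class truth: undefined metrics are NA, not zero
  ms <- evaluate_metrics(c(.9, .8), c(1, 1))
  expect_true(is.na(ms$specificity))
  expect_false(is.na(ms$sensitivity))
  # ties at 0.5 go to the positive class
  mt <- evaluate_metrics(c(0.5, 0.5), c(1, 0))
  expect_equal(mt$sensitivity, 1)
  expect_equal(mt$specificity, 0)
})

test_that("baseline handles carry the tuned hyperparameters", {
  svm <- build_baseline("SVM", tuned = TRUE)
  expect_equal(svm$params$C, 10)
  expect_equal(svm$params$gamma, 0.5)
  expect_equal(svm$params$kernel, "radial")
  lr <- build_baseline("LR", tuned = TRUE)
  expect_equal(lr$params$C, 545.6)
  expect_equal(lr$params$penalty, "elasticnet")
  rf <- build_baseline("RF", tuned = TRUE)
  expect_equal(rf$params$n_trees, 1000L)
  expect_equal(rf$params$max_depth, 40L)
  xgb <- build_baseline("XGBoost", tuned = TRUE)
  expect_equal(xgb$params$n_rounds, 100L)
  expect_equal(xgb$params$learning_rate, 0.1)
  expect_equal(xgb$params$colsample_bytree, 0.75)
  expect_equal(xgb$params$max_depth, 12L)
  expect_false(build_baseline("LR", tuned = FALSE)$tuned)
  expect_error(build_baseline("MLP"), "LR, SVM, RF, XGBoost")
})

test_that("every baseline family separates the phantom classes", {
  ds <- tiny_stage_data(n_per_class = 20, seed = 51)
  test <- tiny_stage_data(n_per_class = 10, seed = 52)
  for (fam in c("LR", "SVM", "RF", "XGBoost")) {
    # smaller forests/rounds keep the check quick; hyperparameters are
    # exercised above
    h <- build_baseline(fam, tuned = fam %in% c("LR", "SVM"))
    if (fam == "RF") h$params$n_trees <- 100L
    if (fam == "XGBoost") h$params$n_rounds <- 20L
    fit <- train_model(h, ds, NULL, train_config(seed = 1))
    m <- evaluate_metrics(fit, test)
    expect_gte(m$accuracy, 0.95)
  }
  nc <- nearest_centroid(ds)
  expect_gte(evaluate_metrics(nc, test)$accuracy, 0.95)
})

test_that("search-space sampling respects the discrete vocabulary", {
  sp <- search_space(n_trials = 5, seed = 9)
  for (s in mrsinet:::child_seeds(5, 40)) {
    cand <- sample_candidate(sp, s)
    expect_true(all(cand$arch$conv_filters %in% c(16, 48, 80, 112, 144)))
    expect_true(all(cand$arch$conv_kernels %in% c(3, 6, 9, 12)))
    expect_true(cand$arch$dense_units %in% seq(64, 512, 64))
    expect_true(length(cand$arch$conv_filters) %in% 2:4)
    expect_gte(cand$learning_rate, 1e-4)
    expect_lte(cand$learning_rate, 1e-2)
  }
  # a degenerate one-point space returns that point
  deg <- search_space(n_layers = 2L, filters = 16L, kernels = 3L,
                      dense_units = 64L, lr_range = c(1e-3, 1e-3),
                      n_trials = 1L, seed = 1)
  cand <- sample_candidate(deg, 77)
  expect_equal(cand$arch$conv_filters, c(16L, 16L))
  expect_equal(cand$learning_rate, 1e-3)
})

test_that("training is deterministic and the single-trial search returns it", {
  small <- tiny_stage_data(n_per_class = 12, seed = 61)
  sp <- mrsinet:::validation_split(small, 0.25, seed = 1)
  arch <- tiny_arch()
  cfg <- train_config(1e-3, batch_size = 8, max_epochs = 2,
                      early_stop_patience = 2, seed = 42)
  f1 <- train_model(build_cnn(arch), sp$fit, sp$val, cfg)
  f2 <- train_model(build_cnn(arch), sp$fit, sp$val, cfg)
  expect_identical(f1$params, f2$params)
  expect_equal(nrow(f1$history), 2)
  expect_true(all(is.finite(f1$history$val_loss)))
  # one-trial random search returns that configuration as best
  deg <- search_space(n_layers = 2L, filters = 16L, kernels = 3L,
                      dense_units = 64L, lr_range = c(1e-3, 1e-3),
                      n_trials = 1L, seed = 5)
  rs <- random_search(deg, sp$fit, sp$val, cfg)
  expect_equal(rs$arch$conv_filters, c(16L, 16L))
  expect_equal(nrow(rs$trials), 1)
  expect_equal(rs$trials$status, "ok")
})
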