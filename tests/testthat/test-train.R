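test_that("stratified split sizes follow the floor rule", {
  set.seed(1)
  labels <- rep(c(0, 1), length.out = 622)
  sp <- stratified_split(labels, c(0.8, 0.1, 0.1), seed = 3)
  expect_length(sp$train, 498)
  expect_length(sp$val, 62)
  expect_length(sp$test, 62)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:622)
  # stratification: class shares preserved in val and test
  expect_equal(sum(labels[sp$val] == 1), 31)
  expect_equal(sum(labels[sp$test] == 1), 31)
  # same seed twice gives the identical split
  sp2 <- stratified_split(labels, c(0.8, 0.1, 0.1), seed = 3)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(labels, c(0.8, 0.1, 0.1), seed = 4)
  expect_false(identical(sp$test, sp3$test))
})

test_that("tiny cohorts fall back with a stratification note", {
  labels <- rep(c(0, 1), each = 5)
  expect_warning(sp <- stratified_split(labels, c(0.8, 0.1, 0.1), seed = 1),
                 "stratification note")
  expect_length(sp$val, 1)
  expect_length(sp$test, 1)
  expect_length(sp$train, 8)
  expect_error(stratified_split(rep(0, 20)), "both classes")
})

test_that("classification metrics match their definitions", {
  m <- classification_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(unlist(m), c(accuracy = 1, f1 = 1, auc = 1))
  # constant 0.5 on a balanced set: ties to class 0, AUC 1/2
  m2 <- classification_metrics(rep(0.5, 4), c(1, 0, 1, 0))
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$auc, 0.5)
  # hand-enumerated pairs: scores (.9,.8,.4,.3), labels (1,0,1,0) -> 3/4
  m3 <- classification_metrics(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(m3$auc, 0.75)
  # single-class evaluation: AUC undefined
  expect_true(is.na(classification_metrics(c(0.2, 0.6), c(1, 1))$auc))
})

test_that("AUC equals the brute-force pair-counting oracle", {
  set.seed(9)
  for (k in 1:20) {
    n <- sample(5:50, 1)
    t <- sample(0:1, n, replace = TRUE)
    if (length(unique(t)) < 2) next
    p <- round(runif(n), 2)       # rounding forces ties
    auc <- classification_metrics(p, t)$auc
    pos <- p[t == 1]; neg <- p[t == 0]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    expect_equal(auc, s / (length(pos) * length(neg)), tolerance = 1e-12)
  }
})

test_that("paired t-test matches the closed form and stats::t.test", {
  r <- paired_ttest(c(2, 3, 4, 5), c(1, 1, 1, 1))  # d = (1,2,3,4)
  expect_equal(r$t, 3.872983, tolerance = 1e-6)
  expect_equal(r$df, 3)
  expect_equal(r$p, 0.030466, tolerance = 1e-4)
  ref <- stats::t.test(c(2, 3, 4, 5), c(1, 1, 1, 1), paired = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  # antisymmetry
  r2 <- paired_ttest(c(1, 1, 1, 1), c(2, 3, 4, 5))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  # degenerate: zero-variance differences are flagged, not given a fake p
  r3 <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_true(r3$degenerate)
  expect_true(is.na(r3$p))
  r4 <- paired_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_true(r4$degenerate)
  expect_equal(r4$p, 0)
})

test_that("repeat summaries use the sample (ddof = 1) convention", {
  rows <- list(list(accuracy = 0.8, f1 = 0.8, auc = 0.8),
               list(accuracy = 0.9, f1 = 0.9, auc = 0.9))
  rep <- mginconn:::summarise_repeats(rows)
  expect_equal(rep$summary$mean[rep$summary$metric == "accuracy"], 0.85)
  expect_equal(rep$summary$sd[rep$summary$metric == "accuracy"],
               0.07071068, tolerance = 1e-6)
})

test_that("zero learning rate leaves parameters and the loss trace flat", {
  tc <- tiny_cohort_graphs(n_per_group = 6, n_rois = 8, timepoints = 40)
  bc <- apply_boxcox_cohort(tc$graphs, 1:12)$graphs
  cfg <- synthetic_train_config(seed = 1, epochs = 30, learning_rate = 0,
                                eval_every = 5, early_stop_loss = 0)
  fit <- train_model(bc, cfg)
  expect_lt(diff(range(fit$trace$train_loss)), 1e-12)
  m0 <- init_mgin(cfg$modalities, 8, layers = 2, hidden_dim = 32, seed = 1)
  expect_equal(fit$final_model$params, m0$params, tolerance = 1e-12)
})

test_that("training is deterministic and fits a separable toy", {
  tc <- tiny_cohort_graphs(n_per_group = 6, n_rois = 8, timepoints = 60,
                           delta = 0.6)
  bc <- apply_boxcox_cohort(tc$graphs, seq_along(tc$graphs))$graphs
  cfg <- synthetic_train_config(seed = 2, epochs = 400, learning_rate = 1e-2,
                                weight_decay = 0, early_stop_loss = 0,
                                hidden_dim = 16)
  fit1 <- train_model(bc, cfg)
  fit2 <- train_model(bc, cfg)
  expect_equal(tail(fit1$trace$train_loss, 1), tail(fit2$trace$train_loss, 1),
               tolerance = 1e-8)
  expect_lt(tail(fit1$trace$train_loss, 1), 0.01)
  expect_equal(evaluate(fit1$model, bc)$accuracy, 1)
})

test_that("experiment audit proves test indices stay untouched before scoring", {
  tc <- tiny_cohort_graphs(n_per_group = 10, n_rois = 8, timepoints = 40)
  cfg <- synthetic_train_config(seed = 5, epochs = 30)
  res <- run_experiment(tc$graphs, cfg, seed = 5)
  expect_length(intersect(res$audit$boxcox_fit_idx, res$split$test), 0)
  expect_length(intersect(res$audit$checkpoint_selection_idx,
                          res$split$test), 0)
  expect_identical(res$audit$test_idx_first_use, "final evaluation")
})

test_that("repeated-experiment and k-fold protocols cover all subjects", {
  tc <- tiny_cohort_graphs(n_per_group = 10, n_rois = 8, timepoints = 40,
                           delta = 0.6)
  cfg <- synthetic_train_config(seed = 7, epochs = 40)
  rep <- bootstrap_protocol(tc$graphs, cfg, repeats = 3)
  expect_equal(nrow(rep$per_repeat), 3)
  expect_true(all(rep$per_repeat$accuracy >= 0 & rep$per_repeat$accuracy <= 1))
  expect_true(all(rep$summary$sd >= 0 | is.na(rep$summary$sd)))

  kf <- kfold_protocol(tc$graphs, cfg, k = 5)
  expect_equal(nrow(kf$per_repeat), 5)
  expect_equal(sort(unique(kf$fold_assignment)), 1:5)
  expect_equal(length(kf$fold_assignment), 20)
  # every subject tested exactly once
  expect_equal(as.numeric(table(kf$fold_assignment)), rep(4, 5))
})

test_that("metrics are invariant to subject order", {
  set.seed(33)
  p <- runif(30); t <- sample(0:1, 30, replace = TRUE)
  perm <- sample(30)
  m1 <- classification_metrics(p, t)
  m2 <- classification_metrics(p[perm], t[perm])
  expect_equal(m1, m2)
})
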