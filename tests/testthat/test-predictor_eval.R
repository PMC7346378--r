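test_that("confusion counts and metrics match the hand-worked example", {
  r <- compute_metrics(truth = c(TRUE, TRUE, FALSE, FALSE),
                       predicted = c(TRUE, FALSE, FALSE, FALSE),
                       scores = c(0.9, 0.4, 0.3, 0.2))
  expect_equal(c(r$tp, r$fn, r$tn, r$fp), c(1, 1, 2, 0))
  expect_equal(r$acc, 0.75)
  expect_equal(r$recall_pos, 0.5)
  expect_equal(r$precision_pos, 1.0)
  expect_equal(r$f1_pos, 2 * (1 * 0.5) / 1.5)
  expect_equal(r$auc, 1.0)
})

test_that("degenerate and perfect predictions are handled", {
  p <- compute_metrics(c(TRUE, FALSE), c(TRUE, FALSE), c(1, 0))
  expect_equal(c(p$acc, p$f1_pos, p$f1_neg, p$auc), c(1, 1, 1, 1))
  d <- compute_metrics(c(TRUE, TRUE, FALSE), c(FALSE, FALSE, FALSE))
  expect_equal(d$recall_pos, 0)
  expect_equal(d$precision_pos, 0)
  expect_true("precision_pos" %in% d$degenerate)
  s <- compute_metrics(c(TRUE, TRUE), c(TRUE, FALSE), c(0.9, 0.1))
  expect_true(is.na(s$auc))  # single-class truth: AUC undefined
})

test_that("metric identities hold on random confusion configurations", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(4:60, 1)
    truth <- runif(n) < 0.5
    if (length(unique(truth)) < 2) next
    pred <- runif(n) < 0.5
    scores <- round(runif(n), 1)  # coarse grid forces score ties
    r <- compute_metrics(truth, pred, scores)
    expect_equal(r$tp + r$fp + r$tn + r$fn, n)
    expect_equal(r$acc, (r$tp + r$tn) / n)
    expect_equal(r$recall_pos, if (r$tp + r$fn > 0) r$tp / (r$tp + r$fn) else 0)
    if (r$precision_pos + r$recall_pos > 0)
      expect_equal(r$f1_pos, 2 * r$precision_pos * r$recall_pos /
                     (r$precision_pos + r$recall_pos))
    # AUC equals all-pairs concordance with half-credit ties
    expect_equal(r$auc, auc_bruteforce(truth, scores))
  }
})

test_that("midrank AUC agrees with an independent reference implementation", {
  set.seed(2)
  truth <- runif(120) < 0.4
  scores <- round(runif(120), 2)
  r <- compute_metrics(truth, scores > 0.5, scores)
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = scores,
                                        quiet = TRUE, direction = "<")))
  expect_equal(r$auc, ref, tolerance = 1e-10)
})

test_that("swapping the positive class swaps metric columns and reflects AUC", {
  set.seed(6)
  truth <- runif(80) < 0.3
  scores <- runif(80)
  pred <- scores > 0.5
  a <- compute_metrics(truth, pred, scores)
  b <- compute_metrics(!truth, !pred, scores)
  expect_equal(b$precision_pos, a$precision_neg)
  expect_equal(b$recall_pos, a$recall_neg)
  expect_equal(b$f1_pos, a$f1_neg)
  expect_equal(b$auc, 1 - a$auc)          # class swap reflects AUC
  expect_equal(compute_metrics(truth, pred, -scores)$auc, 1 - a$auc)  # so does score negation
  expect_equal(compute_metrics(!truth, !pred, -scores)$auc, a$auc)    # both together cancel
})

test_that("stratified splitting is proportional, disjoint and reproducible", {
  y <- rep(c(TRUE, FALSE), c(20, 80))
  sp <- stratified_split(y, 0.8, seed = 4)
  expect_equal(sum(y[sp$train]), 16)
  expect_equal(sum(!y[sp$train]), 64)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  expect_identical(stratified_split(y, 0.8, seed = 4), sp)
  # reference cohort class sizes: 20% test of 273/918 gives ~55 and ~184
  y2 <- rep(c(TRUE, FALSE), c(273, 918))
  sp2 <- stratified_split(y2, 0.8, seed = 4)
  expect_equal(sum(y2[sp2$test]), 273 - round(0.8 * 273))
  expect_equal(sum(!y2[sp2$test]), 918 - round(0.8 * 918))
  expect_error(stratified_split(c(TRUE, FALSE, FALSE), 0.8, seed = 1),
               "at least 2 groups")
})

test_that("group-aware splitting keeps all prefixes of a case together", {
  groups <- rep(sprintf("case%02d", 1:30), each = 4)
  y <- rep(rep(c(TRUE, FALSE), c(10, 20)), each = 4)
  sp <- stratified_split(y, 0.8, seed = 9, groups = groups)
  side <- ifelse(seq_along(y) %in% sp$train, "train", "test")
  expect_true(all(tapply(side, groups, function(s) length(unique(s))) == 1))
})

test_that("a separable toy set is fit perfectly and training is reproducible", {
  toy <- separable_toy()
  for (alg in c("decision_tree", "random_forest")) {
    m <- train_classifier(toy$x, toy$y, model_spec(alg, min_samples_leaf = 1, seed = 2))
    expect_equal(mean(predict(m, toy$x) == toy$y), 1.0)
    m2 <- train_classifier(toy$x, toy$y, model_spec(alg, min_samples_leaf = 1, seed = 2))
    expect_equal(predict(m, toy$x, type = "score"),
                 predict(m2, toy$x, type = "score"))
  }
  expect_error(train_classifier(toy$x, rep(TRUE, length(toy$y))), "single class")
})

test_that("cross-validation folds partition the cases and recompute cleanly", {
  set.seed(14)
  x <- cbind(a = rnorm(300), b = rnorm(300))
  y <- x[, "a"] + rnorm(300, sd = 0.5) > 0
  cv <- cross_validate(x, y, model_spec("decision_tree", seed = 1), k = 5, seed = 3)
  expect_length(cv$folds, 5L)
  sizes <- vapply(cv$folds, function(r) r$tp + r$fp + r$tn + r$fn, numeric(1))
  expect_equal(sum(sizes), 300)
  expect_true(all(abs(sizes - 60) <= 2))
  # each fold's metrics are recomputable from its own confusion counts
  for (r in cv$folds)
    expect_equal(r$acc, (r$tp + r$tn) / (r$tp + r$fp + r$tn + r$fn))
  expect_equal(cv$mean[["acc"]],
               mean(vapply(cv$folds, function(r) r$acc, numeric(1))))
  expect_error(cross_validate(x, y, k = 1), "k must be")
})

test_that("the guideline classifier scores give the balanced-accuracy AUC", {
  rs <- builtin_ruleset()
  snaps <- random_snapshots(400, seed = 44)
  gl <- guideline_as_classifier(snaps, rs)
  truth <- inject_label_noise(gl$predicted, 0.2, seed = 1)
  r <- compute_metrics(truth, gl$predicted, gl$scores)
  expect_equal(r$auc, (r$recall_pos + r$recall_neg) / 2)
  # and when the guideline matches the truth exactly, accuracy is 1
  expect_equal(compute_metrics(gl$predicted, gl$predicted, gl$scores)$acc, 1)
})

test_that("the comparison table has the full model grid plus a guideline row", {
  co <- generate_cohort(cohort_config(n_cases = 220, seed = 21))
  cfg <- default_encoding_config(co$log)
  specs <- list(decision_tree = model_spec("decision_tree", seed = 1),
                random_forest = model_spec("random_forest", seed = 1))
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- run_comparison(co$log, co$snapshots, builtin_ruleset(),
                        "iv_thrombolysis", cfg, specs, k = 3, seed = 2, file = f)
  expect_equal(nrow(tab), 5L)
  expect_equal(sum(tab$model == "guideline"), 1L)
  expect_true(all(c("acc", "auc", "f1_pos", "f1_neg") %in% names(tab)))
  expect_true(all(tab$acc >= 0 & tab$acc <= 1))
  back <- read.csv(f)
  expect_equal(nrow(back), 5L)
  # guideline row accuracy is 1 - nonconformance by construction
  expect_equal(tab$acc[tab$model == "guideline"],
               1 - round(0.126 * 220) / 220)
})
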