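test_that("frequency encoding reproduces the worked two-trace example", {
  wl <- generate_worked_example_log()
  L <- wl$alphabet
  expect_equal(unname(encode_control_flow_frequency(wl$traces[[1]], L)),
               c(1, 2, 1, 1, 0))
  expect_equal(unname(encode_control_flow_frequency(wl$traces[[2]], L)),
               c(1, 0, 1, 1, 1))
  expect_equal(unname(encode_control_flow_frequency(trace("c", character(0)), L)),
               rep(0, 5))
})

test_that("frequency vectors count exactly the in-alphabet events", {
  set.seed(12)
  L <- LETTERS[1:4]
  for (i in 1:25) {
    tr <- trace("c", sample(LETTERS[1:6], sample(0:12, 1), replace = TRUE))
    v <- encode_control_flow_frequency(tr, L)
    expect_equal(sum(v), sum(trace_activities(tr) %in% L))
    for (a in L) expect_equal(v[[a]], sum(trace_activities(tr) == a))
  }
})

test_that("last-state encoding takes the most recent snapshot", {
  wl <- generate_worked_example_log()
  expect_equal(encode_last_state(wl$traces[[1]], "B", "blood_glucose"), 8.3)
  expect_true(is.na(encode_last_state(wl$traces[[2]], "B", "blood_glucose")))
  t1 <- trace("c", "B", payload = data.frame(blood_glucose = 5.5))
  expect_equal(encode_last_state(t1, "B", "blood_glucose"), 5.5)
})

test_that("control-flow-only encoding of the worked example is the 2x5 matrix", {
  wl <- generate_worked_example_log()
  enc <- encode_log(wl, encoding_config(alphabet = wl$alphabet))
  expect_equal(dim(enc$x), c(2L, 5L))
  expect_equal(unname(enc$x), rbind(c(1, 2, 1, 1, 0), c(1, 0, 1, 1, 1)))
  expect_equal(colnames(enc$x), paste0("cf:", wl$alphabet))
})

test_that("feature-vector width does not depend on trace length", {
  traces <- lapply(1:10, function(n)
    trace(paste0("c", n), rep(LETTERS[1:3], length.out = n),
          case_attributes = list(age = 60 + n),
          labels = list(y = n %% 2 == 0)))
  log <- event_log(traces)
  cfg <- encoding_config(alphabet = log$alphabet, case_attributes = "age",
                         event_attributes = list(c("B", "glucose")))
  enc <- encode_log(log, cfg, label_name = "y")
  expect_equal(nrow(enc$x), 10L)
  expect_equal(length(unique(ncol(enc$x))), 1L)
  expect_equal(enc$y, sapply(1:10, function(n) n %% 2 == 0))
  # and without control flow only attribute columns remain
  cfg2 <- cfg; cfg2$use_control_flow <- FALSE
  enc2 <- encode_log(log, cfg2)
  expect_false(any(startsWith(colnames(enc2$x), "cf:")))
  expect_equal(ncol(enc2$x), 3L)  # age + last-state + missing indicator
})

test_that("encoding is deterministic and errors on missing labels", {
  co <- generate_cohort(cohort_config(n_cases = 25, seed = 3))
  cfg <- default_encoding_config(co$log)
  e1 <- encode_log(co$log, cfg, label_name = "iv_thrombolysis")
  e2 <- encode_log(co$log, cfg, label_name = "iv_thrombolysis")
  expect_identical(e1$x, e2$x)
  expect_error(encode_log(co$log, cfg, label_name = "nope"), "missing on case")
})

test_that("categoricals one-hot over training categories; unseen maps to zeros", {
  tr_log <- event_log(list(
    trace("a", "A", case_attributes = list(sex = "female")),
    trace("b", "A", case_attributes = list(sex = "male"))))
  te_log <- event_log(list(trace("z", "A", case_attributes = list(sex = "other"))))
  cfg <- encoding_config(alphabet = "A", case_attributes = "sex")
  fit <- encode_log(tr_log, cfg)$fit
  expect_equal(sort(fit$categories$sex), c("female", "male"))
  te <- encode_log(te_log, cfg, fit = fit)
  expect_equal(unname(te$x[, c("sex=female", "sex=male")]), c(0, 0))
})

test_that("variance selection keeps strictly-above-threshold columns in order", {
  x <- cbind(const = rep(1, 4), low = c(0, 1, 0, 1), high = c(0, 2, 4, 6))
  # hand-computed sample variances: 0, 1/3, 20/3
  expect_equal(colnames(select_features_by_variance(x, 0)), c("low", "high"))
  expect_equal(colnames(select_features_by_variance(x, 1)), "high")
  x2 <- cbind(a = c(0, 0.5, 1, 7), b = c(3, 0, 1, 9))
  expect_equal(select_features_by_variance(x2, 0), x2)  # no constant columns
  expect_error(select_features_by_variance(x, -1), "non-negative")
})

test_that("z-scoring uses training mean and sample SD without clipping", {
  train <- cbind(v = c(0, 2), const = c(5, 5))
  stats <- fit_feature_stats(train)
  z <- normalize_features(train, stats)
  expect_equal(z[, "v"], c(-1, 1) / sqrt(2), tolerance = 1e-12)  # sample SD
  expect_equal(z[, "const"], c(5, 5))  # zero-SD columns pass through
  test <- cbind(v = 10, const = 5)
  zt <- normalize_features(test, stats)
  expect_gt(zt[, "v"], 1)  # training stats applied to test rows, no clipping
})

test_that("median imputation fills last-state gaps and flags them", {
  log <- event_log(list(
    trace("a", "B", payload = data.frame(g = 4)),
    trace("b", "B", payload = data.frame(g = 6)),
    trace("c", "A")))
  cfg <- encoding_config(alphabet = c("B", "A"),
                         event_attributes = list(c("B", "g")))
  enc <- encode_log(log, cfg)
  expect_equal(unname(enc$x[, "B.g"]), c(4, 6, 5))     # median of 4, 6
  expect_equal(unname(enc$x[, "B.g_missing"]), c(0, 0, 1))
  cfg2 <- encoding_config(alphabet = c("B", "A"),
                          event_attributes = list(c("B", "g")),
                          missing_value_policy = "sentinel", sentinel = -1)
  enc2 <- encode_log(log, cfg2)
  expect_equal(unname(enc2$x[, "B.g"]), c(4, 6, -1))
})
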