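#' Classifier specification
#'
#' @param algorithm `"decision_tree"` (rpart) or `"random_forest"` (ranger).
#' @param min_samples_leaf Minimum observations in a terminal node (default
#'   5).
#' @param n_estimators Trees in the forest (default 10; ignored for the
#'   single tree).
#' @param class_weight `"balanced"`: classes are weighted inversely to their
#'   frequency, `n / (2 * n_class)`.
#' @param seed Integer seed making training reproducible.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("random_forest", "decision_tree"),
                       min_samples_leaf = 5L, n_estimators = 10L,
                       class_weight = "balanced", seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (n_estimators < 1L) stop("n_estimators must be >= 1")
  if (min_samples_leaf < 1L) stop("min_samples_leaf must be >= 1")
  structure(list(algorithm = algorithm,
                 min_samples_leaf = as.integer(min_samples_leaf),
                 n_estimators = as.integer(n_estimators),
                 class_weight = class_weight, seed = as.integer(seed)),
            class = "model_spec")
}

.balanced_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  as.numeric(w[as.character(y)])
}

#' Group-aware stratified train/test split
#'
#' Splits at the level of groups (parent cases), so all prefixes of one case
#' land on the same side — no leakage of a case's own future into training.
#' Within each outcome class the groups are sampled proportionally:
#' `round(train_fraction * n_groups_in_class)` go to training.
#'
#' @param y Logical/binary outcome per instance.
#' @param train_fraction Proportion in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @param groups Group id per instance (default: each instance its own
#'   group). All instances of a group must share the same label.
#' @return List with integer vectors `train` and `test` (instance indices).
#' @export
stratified_split <- function(y, train_fraction = 0.8, seed = 1L, groups = NULL) {
  y <- as.logical(y)
  if (!is_scalar_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  groups <- as.character(groups %||% seq_along(y))
  gy <- .group_labels(y, groups)
  if (any(table(gy) < 2L))
    stop("each class needs at least 2 groups to split")
  set.seed(seed)
  train_groups <- character(0)
  for (cl in c(FALSE, TRUE)) {
    g <- names(gy)[gy == cl]
    g <- sample(g)
    train_groups <- c(train_groups, g[seq_len(round(train_fraction * length(g)))])
  }
  train <- which(groups %in% train_groups)
  list(train = train, test = setdiff(seq_along(y), train))
}

.group_labels <- function(y, groups) {
  gy <- tapply(y, groups, function(v) {
    u <- unique(v)
    if (length(u) != 1L) stop("instances of one group carry different labels")
    u
  })
  gy[unique(groups)]
}

#' Train an outcome classifier
#'
#' Fits a decision tree (`rpart`, gini split, `minbucket` as the minimum
#' samples per leaf) or a random forest (`ranger` probability forest,
#' `n_estimators` trees) on an encoded feature matrix, with balanced class
#' weights. The returned object predicts classes and positive-class
#' probability scores via [predict.ppm_classifier()].
#'
#' @param x Numeric feature matrix (named columns).
#' @param y Logical outcome vector.
#' @param spec A [model_spec()].
#' @return An object of class `ppm_classifier`.
#' @export
train_classifier <- function(x, y, spec = model_spec()) {
  y <- as.logical(y)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(df)))
  yf <- factor(y, levels = c(FALSE, TRUE), labels = c("neg", "pos"))
  set.seed(spec$seed)
  if (spec$algorithm == "decision_tree") {
    w <- if (identical(spec$class_weight, "balanced")) .balanced_weights(yf)
         else rep(1, length(yf))
    dat <- cbind(df, .y = yf)
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = rpart::rpart.control(
                          minbucket = spec$min_samples_leaf, cp = 1e-3, xval = 0))
  } else {
    cw <- if (identical(spec$class_weight, "balanced")) {
      tab <- table(yf)
      as.numeric(length(yf) / (2 * tab[c("neg", "pos")]))
    } else c(1, 1)
    fit <- ranger::ranger(x = df, y = yf, num.trees = spec$n_estimators,
                          min.node.size = spec$min_samples_leaf,
                          class.weights = cw, probability = TRUE,
                          seed = spec$seed, num.threads = 1L)
  }
  structure(list(fit = fit, spec = spec, feature_names = colnames(x),
                 n_features = ncol(x)),
            class = "ppm_classifier")
}

#' Predict with a trained classifier
#'
#' @param object A `ppm_classifier`.
#' @param newdata Feature matrix with the training columns.
#' @param type `"class"` for logical predictions (score > 0.5) or `"score"`
#'   for the positive-class probability.
#' @param ... Unused.
#' @export
predict.ppm_classifier <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (ncol(newdata) != object$n_features)
    stop("newdata has ", ncol(newdata), " features; model expects ", object$n_features)
  df <- as.data.frame(newdata)
  names(df) <- paste0("f", seq_len(ncol(df)))
  score <- if (object$spec$algorithm == "decision_tree") {
    stats::predict(object$fit, df, type = "prob")[, "pos"]
  } else {
    stats::predict(object$fit, data = df, num.threads = 1L)$predictions[, "pos"]
  }
  if (type == "score") unname(score) else unname(score > 0.5)
}

#' @export
print.ppm_classifier <- function(x, ...) {
  cat(sprintf("<%s: %d feature(s), min leaf %d%s>\n", x$spec$algorithm,
              x$n_features, x$spec$min_samples_leaf,
              if (x$spec$algorithm == "random_forest")
                sprintf(", %d trees", x$spec$n_estimators) else ""))
  invisible(x)
}

# Midrank AUC: probability a random positive is scored above a random
# negative, ties half-credited.
.auc_midrank <- function(truth, scores) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts and per-class metrics
#'
#' Computes the confusion table of predictions against truth and, from it,
#' accuracy `(TP+TN)/(TP+FP+TN+FN)`, and precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and F1 (harmonic mean) twice — once with the treated class as
#' positive (`*_pos`) and once with the untreated class as positive
#' (`*_neg`). AUC is the midrank statistic over `scores` when given.
#' Zero-denominator metrics are reported as 0 and flagged in `degenerate`.
#'
#' @param truth,predicted Logical vectors of equal length.
#' @param scores Optional numeric scores (higher = more likely positive);
#'   required for AUC.
#' @return An object of class `evaluation_report`.
#' @export
compute_metrics <- function(truth, predicted, scores = NULL) {
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  tp <- sum(truth & predicted); fp <- sum(!truth & predicted)
  tn <- sum(!truth & !predicted); fn <- sum(truth & !predicted)
  degenerate <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); 0 } else num / den
  }
  precision_pos <- safe_div(tp, tp + fp, "precision_pos")
  recall_pos <- safe_div(tp, tp + fn, "recall_pos")
  precision_neg <- safe_div(tn, tn + fn, "precision_neg")
  recall_neg <- safe_div(tn, tn + fp, "recall_neg")
  f1 <- function(p, r, name) {
    if (p + r == 0) { degenerate <<- c(degenerate, name); 0 }
    else 2 * p * r / (p + r)
  }
  auc <- if (is.null(scores)) NA_real_ else .auc_midrank(truth, scores)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 acc = (tp + tn) / (tp + fp + tn + fn),
                 precision_pos = precision_pos, precision_neg = precision_neg,
                 recall_pos = recall_pos, recall_neg = recall_neg,
                 f1_pos = f1(precision_pos, recall_pos, "f1_pos"),
                 f1_neg = f1(precision_neg, recall_neg, "f1_neg"),
                 auc = auc, degenerate = degenerate),
            class = "evaluation_report")
}

.metric_names <- c("acc", "precision_pos", "precision_neg", "recall_pos",
                   "recall_neg", "f1_pos", "f1_neg", "auc")

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat(sprintf("<evaluation: n=%d (tp=%d fp=%d tn=%d fn=%d)>\n",
              x$tp + x$fp + x$tn + x$fn, x$tp, x$fp, x$tn, x$fn))
  v <- vapply(.metric_names, function(m) x[[m]], numeric(1))
  print(round(v, digits))
  invisible(x)
}

#' Turn an evaluation report into a one-row data frame
#' @param report An `evaluation_report`.
#' @export
report_as_row <- function(report) {
  as.data.frame(report[c("tp", "fp", "tn", "fn", .metric_names)])
}

#' Stratified group-aware k-fold cross-validation
#'
#' Groups (parent cases) are assigned to folds class by class, so folds are
#' approximately stratified and all prefixes of one case share a fold. Each
#' fold is evaluated with [compute_metrics()]; the mean report averages every
#' metric over folds (confusion counts are summed).
#'
#' @param x Feature matrix.
#' @param y Logical outcome.
#' @param spec A [model_spec()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param groups Group id per instance (default: each its own).
#' @return List with `folds` (list of `evaluation_report`) and `mean` (named
#'   numeric vector of fold-averaged metrics plus summed counts).
#' @export
cross_validate <- function(x, y, spec = model_spec(), k = 5L, seed = 1L,
                           groups = NULL) {
  y <- as.logical(y)
  if (k < 2L) stop("k must be >= 2")
  groups <- as.character(groups %||% seq_along(y))
  gy <- .group_labels(y, groups)
  set.seed(seed)
  fold_of <- integer(0)
  for (cl in c(FALSE, TRUE)) {
    g <- sample(names(gy)[gy == cl])
    f <- stats::setNames(rep_len(seq_len(k), length(g)), g)
    fold_of <- c(fold_of, f)
  }
  fold <- fold_of[groups]
  reports <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- fold != i; te <- !tr
    if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L)
      stop("fold ", i, " lacks a class; use a smaller k")
    model <- train_classifier(x[tr, , drop = FALSE], y[tr], spec)
    scores <- predict(model, x[te, , drop = FALSE], type = "score")
    reports[[i]] <- compute_metrics(y[te], scores > 0.5, scores)
  }
  means <- vapply(.metric_names, function(m)
    mean(vapply(reports, function(r) r[[m]], numeric(1))), numeric(1))
  counts <- vapply(c("tp", "fp", "tn", "fn"), function(m)
    sum(vapply(reports, function(r) r[[m]], numeric(1))), numeric(1))
  list(folds = reports, mean = c(counts, means))
}

#' Treat a guideline rule set as a classifier
#'
#' Predicted label is the rule-set recommendation; the score is 1 for
#' recommended, 0 otherwise. With a two-valued score the midrank AUC has the
#' closed form `(recall_pos + recall_neg) / 2`, i.e. balanced accuracy.
#'
#' @param snapshots Data frame of patient snapshots.
#' @param ruleset A `ppm_ruleset`.
#' @param missing_policy See [evaluate_rules()].
#' @return List with `predicted` (logical) and `scores` (0/1 numeric).
#' @export
guideline_as_classifier <- function(snapshots, ruleset,
                                    missing_policy = "strict") {
  rec <- recommend_cohort(snapshots, ruleset, missing_policy)
  list(predicted = rec, scores = as.numeric(rec))
}

#' Compare learned models against the guideline recommender
#'
#' Runs decision tree and random forest, each with and without the
#' control-flow block, under stratified group-aware k-fold cross-validation,
#' and adds the guideline-as-classifier row evaluated on the same cases. One
#' row per model with accuracy, per-class precision/recall/F1 and AUC.
#'
#' @param log A labelled `ppm_event_log` (typically a prefix log).
#' @param snapshots Data frame of patient snapshots aligned with the log's
#'   parent cases (row order = cohort case order, `case_id` column).
#' @param ruleset A `ppm_ruleset`.
#' @param label_name Outcome label to predict.
#' @param config An [encoding_config()] (its `use_control_flow` is overridden
#'   per row).
#' @param specs Named list of [model_spec()]s, default a decision tree and a
#'   random forest.
#' @param k,seed Cross-validation folds and seed.
#' @param file Optional path; when given the table is also written as CSV.
#' @return Data frame, one row per model variant plus the guideline row.
#' @export
run_comparison <- function(log, snapshots, ruleset, label_name, config,
                           specs = list(
                             decision_tree = model_spec("decision_tree"),
                             random_forest = model_spec("random_forest")),
                           k = 5L, seed = 1L, file = NULL) {
  treated <- vapply(log$traces, function(t) isTRUE(t$labels[[label_name]]), logical(1))
  rows <- list()
  for (nm in names(specs)) {
    for (cf in c(FALSE, TRUE)) {
      cfg <- config; cfg$use_control_flow <- cf
      enc <- encode_log(log, cfg, label_name = label_name)
      cv <- cross_validate(enc$x, enc$y, specs[[nm]], k = k, seed = seed,
                           groups = enc$group_ids)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(model = nm, control_flow = cf, stringsAsFactors = FALSE),
        as.data.frame(as.list(cv$mean[.metric_names])))
    }
  }
  gl <- guideline_as_classifier(snapshots, ruleset)
  idx <- match(vapply(log$traces, function(t) t$parent_case_id %||% t$case_id,
                      character(1)), snapshots$case_id)
  rep_gl <- compute_metrics(treated, gl$predicted[idx], gl$scores[idx])
  rows[[length(rows) + 1L]] <- cbind(
    data.frame(model = "guideline", control_flow = NA, stringsAsFactors = FALSE),
    report_as_row(rep_gl)[, .metric_names])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
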