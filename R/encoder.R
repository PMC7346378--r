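#' Encoding configuration
#'
#' Describes how a (prefix) trace is turned into a fixed-length numeric
#' feature vector:
#' control-flow frequency counts over the ordered alphabet, static case
#' attributes (categoricals one-hot over training categories, logicals as
#' 0/1), and last-state event attributes (the payload value at the most
#' recent occurrence of an activity). The vector length depends only on the
#' configuration — never on the trace length — which is what makes prefixes of
#' different lengths comparable to a classifier.
#'
#' @param alphabet Ordered activity names for the frequency block (required
#'   when `use_control_flow = TRUE`).
#' @param case_attributes Ordered character vector of static attribute names.
#' @param event_attributes List of `c(activity, attribute)` pairs for
#'   last-state extraction.
#' @param use_control_flow Include the frequency block? (`FALSE` gives the
#'   "without control flow" ablation.)
#' @param missing_value_policy `"median_impute"` (training median plus a 0/1
#'   missing-indicator column) or `"sentinel"` (a fixed value, no indicator).
#' @param sentinel Sentinel value used under the sentinel policy (default 0).
#' @param normalize `"none"` (default; tree models are scale-invariant) or
#'   `"zscore"` (per-column standardization with training mean / sample SD).
#' @return An object of class `encoding_config`.
#' @export
encoding_config <- function(alphabet = character(0),
                            case_attributes = character(0),
                            event_attributes = list(),
                            use_control_flow = TRUE,
                            missing_value_policy = c("median_impute", "sentinel"),
                            sentinel = 0,
                            normalize = c("none", "zscore")) {
  missing_value_policy <- match.arg(missing_value_policy)
  normalize <- match.arg(normalize)
  if (use_control_flow && !length(alphabet))
    stop("alphabet must be non-empty when use_control_flow is TRUE")
  structure(list(alphabet = as.character(alphabet),
                 case_attributes = as.character(case_attributes),
                 event_attributes = event_attributes,
                 use_control_flow = isTRUE(use_control_flow),
                 missing_value_policy = missing_value_policy,
                 sentinel = sentinel,
                 normalize = normalize),
            class = "encoding_config")
}

#' Frequency-encode the control flow of a trace
#'
#' Position `i` of the result counts how often `alphabet[i]` occurs in the
#' trace; activities outside the alphabet are ignored. For the worked pair
#' t1 = A,B,C,D,B and t2 = A,C,D,E over L = A,B,C,D,E this gives
#' `c(1,2,1,1,0)` and `c(1,0,1,1,1)`.
#'
#' @param x A `ppm_trace`.
#' @param alphabet Ordered character vector of activity names.
#' @return Named numeric vector of counts, one per alphabet entry.
#' @export
encode_control_flow_frequency <- function(x, alphabet) {
  acts <- trace_activities(x)
  counts <- vapply(alphabet, function(a) sum(acts == a), numeric(1))
  names(counts) <- alphabet
  counts
}

#' Last-state encoding of an event attribute
#'
#' Returns the payload value of `attribute` on the last occurrence of
#' `activity` in the trace (the most recent snapshot of a dynamic value, e.g.
#' the latest blood glucose). Returns `NA` when the activity never occurs or
#' does not carry the attribute; [encode_log()] applies the configured
#' missing-value policy to these.
#'
#' @param x A `ppm_trace`.
#' @param activity,attribute Activity and payload attribute names.
#' @return The payload value, or `NA`.
#' @export
encode_last_state <- function(x, activity, attribute) {
  idx <- which(trace_activities(x) == activity)
  if (!length(idx) || !attribute %in% names(x$events)) return(NA)
  x$events[[attribute]][idx[length(idx)]]
}

#' Encode an event log as a feature matrix
#'
#' One row per trace: `[control-flow frequencies] ++ [case attributes] ++
#' [last-state event attributes]` in the deterministic column order implied by
#' the configuration. Categorical case attributes are one-hot encoded over the
#' categories observed when the encoding was fitted; unseen categories map to
#' all-zero blocks. Missing numeric values follow the configured policy
#' (training-median imputation adds a companion `*_missing` indicator for
#' last-state features). Pass the `fit` of a training encode to encode test
#' data with training categories, medians and normalization statistics.
#'
#' @param log A `ppm_event_log`.
#' @param config An [encoding_config()].
#' @param label_name Optional outcome-label name; when given, every trace must
#'   carry it and the label vector is returned.
#' @param fit Optional fit object from a previous `encode_log()` call.
#' @return List with `x` (numeric matrix with column names), `y` (logical
#'   labels or `NULL`), `case_ids`, `group_ids` (parent case ids for prefix
#'   traces) and `fit`.
#' @export
encode_log <- function(log, config, label_name = NULL, fit = NULL) {
  traces <- log$traces
  n <- length(traces)

  y <- NULL
  if (!is.null(label_name)) {
    y <- vapply(traces, function(t) {
      v <- t$labels[[label_name]]
      if (is.null(v)) NA else as.logical(v)
    }, logical(1))
    if (anyNA(y)) {
      miss <- vapply(traces, function(t) t$case_id, character(1))[is.na(y)]
      stop("label '", label_name, "' missing on case(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
  }

  # raw attribute columns before numeric expansion
  raw_case <- lapply(config$case_attributes, function(a)
    sapply(traces, function(t) {
      v <- t$case_attributes[[a]]
      if (is.null(v) || length(v) != 1L) NA else v
    }, simplify = TRUE))
  names(raw_case) <- config$case_attributes

  raw_last <- lapply(config$event_attributes, function(pair)
    vapply(traces, function(t) {
      v <- encode_last_state(t, pair[[1]], pair[[2]])
      if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
    }, numeric(1)))
  names(raw_last) <- vapply(config$event_attributes,
                            function(p) paste0(p[[1]], ".", p[[2]]), character(1))

  if (is.null(fit)) fit <- .fit_encoding(raw_case, raw_last, config)

  blocks <- list()
  if (config$use_control_flow) {
    freq <- vapply(traces, encode_control_flow_frequency,
                   numeric(length(config$alphabet)), alphabet = config$alphabet)
    freq <- t(matrix(freq, nrow = length(config$alphabet), ncol = n))
    colnames(freq) <- paste0("cf:", config$alphabet)
    blocks$cf <- freq
  }
  for (a in config$case_attributes)
    blocks[[paste0("case_", a)]] <- .expand_case_attr(raw_case[[a]], a, fit, config, n)
  for (nm in names(raw_last))
    blocks[[paste0("last_", nm)]] <- .expand_last_state(raw_last[[nm]], nm, fit, config, n)

  x <- if (length(blocks)) do.call(cbind, unname(blocks)) else matrix(numeric(0), n, 0)
  rownames(x) <- NULL

  if (config$normalize == "zscore") {
    if (is.null(fit$norm_stats)) fit$norm_stats <- fit_feature_stats(x)
    x <- normalize_features(x, fit$norm_stats)
  }

  list(x = x, y = y,
       case_ids = vapply(traces, function(t) t$case_id, character(1)),
       group_ids = vapply(traces, function(t) t$parent_case_id %||% t$case_id,
                          character(1)),
       fit = fit)
}

.fit_encoding <- function(raw_case, raw_last, config) {
  fit <- list(case_kind = list(), categories = list(), medians = list(),
              norm_stats = NULL)
  for (a in names(raw_case)) {
    v <- raw_case[[a]]
    if (is.logical(v)) {
      fit$case_kind[[a]] <- "logical"
    } else if (is.numeric(v)) {
      fit$case_kind[[a]] <- "numeric"
      fit$medians[[a]] <- stats::median(v, na.rm = TRUE)
    } else {
      fit$case_kind[[a]] <- "categorical"
      fit$categories[[a]] <- sort(unique(stats::na.omit(as.character(v))))
    }
  }
  for (nm in names(raw_last))
    fit$medians[[nm]] <- stats::median(raw_last[[nm]], na.rm = TRUE)
  fit
}

.impute <- function(v, key, fit, config) {
  miss <- is.na(v)
  if (any(miss)) {
    if (config$missing_value_policy == "sentinel") {
      v[miss] <- config$sentinel
    } else {
      med <- fit$medians[[key]]
      v[miss] <- if (is.null(med) || is.na(med)) config$sentinel else med
    }
  }
  v
}

.expand_case_attr <- function(v, a, fit, config, n) {
  kind <- fit$case_kind[[a]] %||% "numeric"
  if (kind == "logical") {
    m <- matrix(as.numeric(.impute(as.logical(v), a, fit, config)), ncol = 1)
    colnames(m) <- a
  } else if (kind == "numeric") {
    m <- matrix(.impute(suppressWarnings(as.numeric(v)), a, fit, config), ncol = 1)
    colnames(m) <- a
  } else {
    cats <- fit$categories[[a]]
    m <- matrix(0, n, length(cats),
                dimnames = list(NULL, if (length(cats)) paste0(a, "=", cats)
                                      else character(0)))
    for (j in seq_along(cats))
      m[, j] <- as.numeric(!is.na(v) & as.character(v) == cats[j])
  }
  m
}

.expand_last_state <- function(v, nm, fit, config, n) {
  miss <- as.numeric(is.na(v))
  vals <- .impute(v, nm, fit, config)
  if (config$missing_value_policy == "median_impute") {
    m <- cbind(vals, miss)
    colnames(m) <- c(nm, paste0(nm, "_missing"))
  } else {
    m <- matrix(vals, ncol = 1)
    colnames(m) <- nm
  }
  m
}

#' Drop low-variance feature columns
#'
#' Keeps the columns whose sample variance is strictly greater than
#' `threshold` (default 0: drop constant columns only), preserving column
#' order. The kept feature names are the column names of the result.
#'
#' @param x Numeric feature matrix with column names.
#' @param threshold Non-negative variance threshold.
#' @return The filtered matrix.
#' @export
select_features_by_variance <- function(x, threshold = 0) {
  if (!is.matrix(x) || nrow(x) == 0L) stop("x must be a non-empty matrix")
  if (!is_scalar_number(threshold) || threshold < 0)
    stop("threshold must be a non-negative number")
  v <- apply(x, 2, stats::var)
  v[is.na(v)] <- 0
  x[, v > threshold, drop = FALSE]
}

#' Per-column mean and sample standard deviation
#'
#' Computed on training rows only; feed the result to [normalize_features()]
#' for both the training and the test matrix.
#'
#' @param x Numeric training matrix.
#' @return List with `mean` and `sd` vectors.
#' @export
fit_feature_stats <- function(x) {
  list(mean = colMeans(x), sd = apply(x, 2, stats::sd))
}

#' Z-score features with training statistics
#'
#' Subtracts the training mean and divides by the training sample SD, column
#' by column. Zero-SD (constant) columns pass through unchanged; test values
#' may fall outside \[-1, 1\] — no clipping.
#'
#' @param x Numeric matrix to transform.
#' @param stats Output of [fit_feature_stats()] on the training rows.
#' @return Transformed matrix.
#' @export
normalize_features <- function(x, stats) {
  for (j in seq_len(ncol(x))) {
    s <- stats$sd[j]
    if (!is.na(s) && s > 0) x[, j] <- (x[, j] - stats$mean[j]) / s
  }
  x
}
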