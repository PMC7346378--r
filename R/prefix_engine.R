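#' Prefix-extraction configuration
#'
#' Controls which leading partial traces (prefixes) are generated from each
#' completed trace. With the defaults, a completed trace of `n` events yields
#' its `n - 1` proper prefixes: the complete trace itself is excluded, because
#' prediction targets running cases whose outcome is still open.
#'
#' @param min_length Smallest prefix length to keep (default 1).
#' @param max_length Largest prefix length to keep (default `Inf`, unlimited).
#' @param include_complete Should the complete trace itself count as a prefix?
#'   Default `FALSE`.
#' @param selected_activities Optional ordered subset of the alphabet; when
#'   set, [build_prefix_log()] first restricts the control flow to these
#'   activities (see [filter_activities()]).
#' @return An object of class `prefix_config`.
#' @export
prefix_config <- function(min_length = 1L, max_length = Inf,
                          include_complete = FALSE,
                          selected_activities = NULL) {
  min_length <- as.integer(min_length)
  if (min_length < 1L) stop("min_length must be a positive integer")
  if (is.finite(max_length)) {
    max_length <- as.integer(max_length)
    if (min_length > max_length) stop("min_length must not exceed max_length")
  }
  structure(list(min_length = min_length, max_length = max_length,
                 include_complete = isTRUE(include_complete),
                 selected_activities = selected_activities),
            class = "prefix_config")
}

#' Extract the prefixes of a completed trace
#'
#' Returns the leading partial traces of lengths `min_length` up to
#' `min(max_length, n - 1)` (or `n` when `include_complete = TRUE`), where `n`
#' is the number of events. Each prefix shares the parent's case id, case
#' attributes and outcome labels, so prefixes are labelled training instances.
#'
#' @param x A `ppm_trace` with at least one event.
#' @param config A [prefix_config()].
#' @return List of `ppm_trace` prefixes (possibly empty).
#' @export
extract_prefixes <- function(x, config = prefix_config()) {
  n <- trace_length(x)
  if (n == 0L) stop("cannot extract prefixes of an empty trace (case ", x$case_id, ")")
  top <- if (config$include_complete) n else n - 1L
  top <- min(top, config$max_length)
  lens <- seq_len(max(top, 0L))
  lens <- lens[lens >= config$min_length]
  lapply(lens, function(k) {
    p <- x
    p$events <- x$events[seq_len(k), , drop = FALSE]
    p
  })
}

#' Build a prefix log from a log of completed traces
#'
#' Concatenates [extract_prefixes()] over all traces. Prefix case ids are the
#' parent case id suffixed with `_<length>` so they stay unique; the parent id
#' is retained in the trace's `parent_case_id` field for group-aware
#' train/test splitting. When `config$selected_activities` is set, the control
#' flow is first filtered to those activities. Traces with no events after
#' filtering contribute no prefixes.
#'
#' @param log A `ppm_event_log`.
#' @param config A [prefix_config()].
#' @return A `ppm_event_log` of prefix traces (alphabet inherited).
#' @export
build_prefix_log <- function(log, config = prefix_config()) {
  if (!is.null(config$selected_activities))
    log <- filter_activities(log, config$selected_activities)
  prefixes <- list()
  for (t in log$traces) {
    if (trace_length(t) == 0L) next
    for (p in extract_prefixes(t, config)) {
      p$parent_case_id <- t$case_id
      p$case_id <- paste0(t$case_id, "_", trace_length(p))
      prefixes[[length(prefixes) + 1L]] <- p
    }
  }
  out <- event_log(prefixes, alphabet = if (length(prefixes)) log$alphabet else NULL)
  out$alphabet <- log$alphabet
  out
}

#' Restrict a log's control flow to a subset of activities
#'
#' Every trace keeps only events whose activity is in `keep` (order
#' preserved); the alphabet is restricted to `keep` in its original alphabet
#' order. Traces left with zero events are retained — they still carry case
#' attributes and labels for encoding.
#'
#' @param log A `ppm_event_log`.
#' @param keep Character vector of activity names, a subset of the alphabet.
#' @return A filtered `ppm_event_log`.
#' @export
filter_activities <- function(log, keep) {
  keep <- as.character(keep)
  unknown <- setdiff(keep, log$alphabet)
  if (length(unknown))
    stop("unknown activity in keep set: ", paste(unknown, collapse = ", "))
  traces <- lapply(log$traces, function(t) {
    sel <- t$events$activity %in% keep
    t$events <- t$events[sel, , drop = FALSE]
    rownames(t$events) <- NULL
    t
  })
  out <- event_log(traces, alphabet = log$alphabet[log$alphabet %in% keep])
  out
}
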