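#' Construct a clinical trace
#'
#' A trace is the ordered sequence of events for one case (one patient
#' admission), together with its static case attributes and optional boolean
#' outcome labels (e.g. whether intravenous thrombolysis was performed).
#' Events are sorted by timestamp; ties keep their input order.
#'
#' @param case_id Single non-empty string identifying the case.
#' @param activities Character vector of activity names (one per event).
#' @param timestamps `POSIXct` vector aligned with `activities`. Defaults to
#'   one-minute spacing from a fixed epoch, which is convenient for fixtures.
#' @param payload Optional data frame (or named list of vectors) of event
#'   attributes, one row/element per event; `NA` where an event does not carry
#'   the attribute.
#' @param case_attributes Named list of static attributes (age, admission
#'   glucose, history flags, ...).
#' @param labels Named list of logical outcome labels.
#' @return An object of class `ppm_trace`.
#' @export
trace <- function(case_id, activities, timestamps = NULL, payload = NULL,
                  case_attributes = list(), labels = list()) {
  if (!is.character(case_id) || length(case_id) != 1L || !nzchar(case_id))
    stop("case_id must be a single non-empty string")
  activities <- as.character(activities)
  if (length(activities) && any(is.na(activities) | !nzchar(activities)))
    stop("activity names must be non-empty")
  n <- length(activities)
  if (is.null(timestamps)) {
    timestamps <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC") + 60 * seq_len(n)
  }
  if (length(timestamps) != n) stop("timestamps must align with activities")
  events <- data.frame(activity = activities, timestamp = timestamps,
                       stringsAsFactors = FALSE)
  if (!is.null(payload)) {
    payload <- as.data.frame(payload, stringsAsFactors = FALSE, optional = TRUE)
    if (nrow(payload) != n) stop("payload must have one row per event")
    if (anyDuplicated(names(payload))) stop("payload attribute names must be unique")
    events <- cbind(events, payload)
  }
  if (n > 1L) {
    ord <- order(events$timestamp)      # radix sort: stable on ties
    events <- events[ord, , drop = FALSE]
  }
  rownames(events) <- NULL
  structure(list(case_id = case_id, events = events,
                 case_attributes = as.list(case_attributes),
                 labels = as.list(labels)),
            class = "ppm_trace")
}

#' Number of events in a trace
#' @param x A `ppm_trace`.
#' @export
trace_length <- function(x) nrow(x$events)

#' Activity sequence of a trace
#' @param x A `ppm_trace`.
#' @export
trace_activities <- function(x) x$events$activity

#' @export
print.ppm_trace <- function(x, ...) {
  cat(sprintf("<trace %s: %d event(s)> %s\n", x$case_id, trace_length(x),
              paste(trace_activities(x), collapse = " -> ")))
  invisible(x)
}

#' Construct an event log
#'
#' An event log is a collection of traces plus the ordered activity alphabet
#' used for control-flow encoding. If `alphabet` is not supplied it is derived
#' with [derive_alphabet()] (first occurrence across traces in input order).
#'
#' @param traces List of [trace()] objects with unique case ids.
#' @param alphabet Optional explicit ordered character vector; must contain
#'   every activity present in `traces` exactly once.
#' @return An object of class `ppm_event_log`.
#' @export
event_log <- function(traces = list(), alphabet = NULL) {
  if (inherits(traces, "ppm_trace")) traces <- list(traces)
  ids <- vapply(traces, function(t) t$case_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate case_id in event log: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  log <- structure(list(traces = traces, alphabet = character(0)),
                   class = "ppm_event_log")
  seen <- derive_alphabet(log)
  if (is.null(alphabet)) {
    alphabet <- seen
  } else {
    alphabet <- as.character(alphabet)
    if (anyDuplicated(alphabet)) stop("alphabet entries must be distinct")
    missing <- setdiff(seen, alphabet)
    if (length(missing))
      stop("alphabet is missing activities present in the log: ",
           paste(missing, collapse = ", "))
  }
  log$alphabet <- alphabet
  log
}

#' Derive the ordered activity alphabet of a log
#'
#' Each distinct activity appears exactly once, ordered by first occurrence
#' scanning traces in input order and events in time order. The derivation is
#' idempotent and deterministic for a given log.
#'
#' @param log A `ppm_event_log`.
#' @return Character vector of activity names.
#' @export
derive_alphabet <- function(log) {
  acts <- unlist(lapply(log$traces, trace_activities), use.names = FALSE)
  unique(acts) %||% character(0)
}

#' @export
print.ppm_event_log <- function(x, ...) {
  cat(sprintf("<event log: %d trace(s), alphabet [%s]>\n",
              length(x$traces), paste(x$alphabet, collapse = ", ")))
  invisible(x)
}

#' Number of traces in a log
#' @param log A `ppm_event_log`.
#' @export
n_traces <- function(log) length(log$traces)

.reserved_event_cols <- c("case_id", "activity", "timestamp")

#' Read an event log from an events/cases CSV pair
#'
#' The events table has one row per event with columns
#' `case_id,activity,timestamp[,attr...]`; the cases table has one row per
#' case with columns `case_id[,attr...]` and optional outcome-label columns
#' named `label:<name>` holding 0/1. Timestamps are ISO-8601
#' (`YYYY-MM-DDTHH:MM:SS`, UTC). Payload and case-attribute columns are typed
#' by `schema` when given, otherwise numeric if every non-missing value parses
#' as a number, else categorical (character). Duplicate
#' `(case_id, timestamp, activity)` rows are kept in stable input order.
#'
#' @param events_source,cases_source File paths (or connections) of the two
#'   CSV tables.
#' @param schema Optional named character vector / list mapping attribute name
#'   to `"numeric"`, `"categorical"` or `"text"` (the latter two are both
#'   carried as character).
#' @return A `ppm_event_log`.
#' @export
read_event_log <- function(events_source, cases_source, schema = NULL) {
  ev <- utils::read.csv(events_source, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  cs <- utils::read.csv(cases_source, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  for (col in c("case_id", "activity", "timestamp"))
    if (!col %in% names(ev)) stop("events table lacks required column '", col, "'")
  if (!"case_id" %in% names(cs)) stop("cases table lacks required column 'case_id'")

  ev$timestamp <- parse_timestamp(ev$timestamp)
  payload_cols <- setdiff(names(ev), .reserved_event_cols)
  for (col in payload_cols) ev[[col]] <- .apply_schema(ev[[col]], col, schema)

  label_cols <- grep("^label:", names(cs), value = TRUE)
  attr_cols <- setdiff(names(cs), c("case_id", label_cols))
  for (col in attr_cols) cs[[col]] <- .apply_schema(cs[[col]], col, schema)
  for (col in label_cols) cs[[col]] <- as.integer(cs[[col]]) > 0L

  orphan <- setdiff(unique(ev$case_id), cs$case_id)
  if (length(orphan))
    stop("case(s) present in events but absent from cases table: ",
         paste(orphan, collapse = ", "))

  traces <- lapply(seq_len(nrow(cs)), function(i) {
    id <- cs$case_id[i]
    rows <- ev[ev$case_id == id, , drop = FALSE]
    attrs <- as.list(cs[i, attr_cols, drop = FALSE])
    labels <- as.list(cs[i, label_cols, drop = FALSE])
    names(labels) <- sub("^label:", "", names(labels))
    trace(id,
          activities = rows$activity,
          timestamps = rows$timestamp,
          payload = if (length(payload_cols) && nrow(rows))
            rows[, payload_cols, drop = FALSE] else NULL,
          case_attributes = attrs, labels = labels)
  })
  event_log(traces)
}

.apply_schema <- function(x, col, schema) {
  if (!is.null(schema) && !is.null(schema[[col]])) {
    if (schema[[col]] == "numeric") {
      out <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(out) & !is.na(x) & nzchar(x))
      if (length(bad))
        stop(sprintf("column '%s' declared numeric but row %d holds '%s'",
                     col, bad[1], x[bad[1]]))
      out
    } else {
      x[!nzchar(x)] <- NA_character_
      x
    }
  } else {
    infer_column_type(x)
  }
}

#' Write an event log to an events/cases CSV pair
#'
#' Inverse of [read_event_log()]: reading the written pair reproduces
#' activities, timestamps, payloads, case attributes and labels.
#'
#' @param log A `ppm_event_log`.
#' @param events_dest,cases_dest Destination file paths (or connections).
#' @export
write_event_log <- function(log, events_dest, cases_dest) {
  payload_cols <- as.character(unique(unlist(lapply(log$traces, function(t)
    setdiff(names(t$events), c("activity", "timestamp"))))))
  attr_cols <- as.character(unique(unlist(lapply(log$traces, function(t)
    names(t$case_attributes)))))
  label_cols <- as.character(unique(unlist(lapply(log$traces, function(t)
    names(t$labels)))))

  ev_rows <- lapply(log$traces, function(t) {
    n <- trace_length(t)
    if (n == 0L) return(NULL)
    row <- data.frame(case_id = rep(t$case_id, n),
                      activity = t$events$activity,
                      timestamp = format_timestamp(t$events$timestamp),
                      stringsAsFactors = FALSE)
    for (col in payload_cols)
      row[[col]] <- if (col %in% names(t$events)) t$events[[col]] else NA
    row
  })
  ev <- do.call(rbind, ev_rows) %||%
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 3 + length(payload_cols))),
                    c(.reserved_event_cols, payload_cols))

  cs_rows <- lapply(log$traces, function(t) {
    row <- data.frame(case_id = t$case_id, stringsAsFactors = FALSE)
    for (col in attr_cols)
      row[[col]] <- t$case_attributes[[col]] %||% NA
    for (col in label_cols)
      row[[paste0("label:", col)]] <- as.integer(t$labels[[col]] %||% NA)
    row
  })
  label_hdr <- if (length(label_cols)) paste0("label:", label_cols) else character(0)
  cs <- do.call(rbind, cs_rows) %||%
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 1 + length(attr_cols) + length(label_hdr))),
                    c("case_id", attr_cols, label_hdr))

  utils::write.csv(ev, events_dest, row.names = FALSE, na = "")
  utils::write.csv(cs, cases_dest, row.names = FALSE, na = "")
  invisible(NULL)
}
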