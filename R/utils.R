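`%||%` <- function(x, y) if (is.null(x)) y else x

# ISO-8601 (seconds resolution, UTC) used for all serialized timestamps
.ts_format <- "%Y-%m-%dT%H:%M:%S"

format_timestamp <- function(x) format(x, .ts_format, tz = "UTC")

parse_timestamp <- function(x) {
  out <- as.POSIXct(as.character(x), format = .ts_format, tz = "UTC")
  bad <- which(is.na(out) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad)) {
    stop(sprintf("malformed timestamp at row %d: '%s' (expected %s)",
                 bad[1], as.character(x)[bad[1]], .ts_format), call. = FALSE)
  }
  out
}

# logical if all TRUE/FALSE, numeric if every non-missing value parses as a
# number, else left as character
infer_column_type <- function(x) {
  x <- as.character(x)
  x[!nzchar(x)] <- NA_character_
  if (all(is.na(x))) return(x)
  if (all(is.na(x) | x %in% c("TRUE", "FALSE"))) return(as.logical(x))
  num <- suppressWarnings(as.numeric(x))
  if (all(is.na(num) == is.na(x))) num else x
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
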