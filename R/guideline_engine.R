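#' Snapshot fields understood by the rule engine
#'
#' Names and kinds of the per-patient fields a rule predicate may reference:
#' numeric measurements (age, onset-to-consultation time, glucose, platelet
#' count, blood pressure, INR, prothrombin time, neurological-deficit score)
#' and boolean history/status flags.
#'
#' @return Named character vector mapping field name to `"numeric"` or
#'   `"flag"`.
#' @export
snapshot_fields <- function() {
  c(age = "numeric", onset_to_consult = "numeric", glucose = "numeric",
    platelet_count = "numeric", systolic_bp = "numeric",
    diastolic_bp = "numeric", inr = "numeric", pt = "numeric",
    neuro_deficit_score = "numeric",
    ischemic_deficit = "flag", consent_signed = "flag",
    intracranial_hemorrhage = "flag", history_ich = "flag",
    stroke_or_head_injury_3mo = "flag",
    intracranial_neoplasm_or_aneurysm = "flag",
    intracranial_spinal_surgery_3mo = "flag", major_surgery_2wk = "flag",
    gi_or_urinary_bleed_3wk = "flag", active_visceral_hemorrhage = "flag",
    aortic_arch_dissection = "flag",
    recent_difficult_arterial_puncture_1wk = "flag", lmwh_24h = "flag",
    thrombin_or_xa_inhibitor_48h = "flag", abnormal_lab = "flag",
    large_infarct_area = "flag")
}

#' Construct a patient snapshot
#'
#' One-row data frame of the state of a patient at decision time. Defaults
#' describe an eligible patient (all contraindication flags `FALSE`,
#' measurements in normal range) so tests and examples only state what
#' deviates. Numeric fields must be non-negative; `NA` marks a missing value.
#'
#' @param age Years.
#' @param onset_to_consult Hours from symptom onset to consultation (OTC).
#' @param glucose Blood glucose, mmol/L.
#' @param platelet_count Platelets, 10^9/L.
#' @param systolic_bp,diastolic_bp Blood pressure, mmHg.
#' @param inr International normalized ratio.
#' @param pt Prothrombin time, seconds.
#' @param neuro_deficit_score Prehospital neurological-deficit severity score
#'   (FAST-ED-like, 0-9).
#' @param ischemic_deficit,consent_signed Indication flags.
#' @param ... Contraindication flags (see [snapshot_fields()]), default
#'   `FALSE`.
#' @return One-row `data.frame` with class `patient_snapshot`.
#' @export
patient_snapshot <- function(age = 70, onset_to_consult = 2.5, glucose = 6,
                             platelet_count = 200, systolic_bp = 150,
                             diastolic_bp = 80, inr = 1.0, pt = 12,
                             neuro_deficit_score = 4,
                             ischemic_deficit = TRUE, consent_signed = TRUE,
                             ...) {
  fields <- snapshot_fields()
  out <- list(age = age, onset_to_consult = onset_to_consult,
              glucose = glucose, platelet_count = platelet_count,
              systolic_bp = systolic_bp, diastolic_bp = diastolic_bp,
              inr = inr, pt = pt, neuro_deficit_score = neuro_deficit_score,
              ischemic_deficit = ischemic_deficit,
              consent_signed = consent_signed)
  extra <- list(...)
  unknown <- setdiff(names(extra), names(fields))
  if (length(unknown))
    stop("unknown snapshot field(s): ", paste(unknown, collapse = ", "))
  flags <- setdiff(names(fields)[fields == "flag"], names(out))
  for (f in flags) out[[f]] <- FALSE
  out[names(extra)] <- extra
  num <- names(fields)[fields == "numeric"]
  bad <- num[vapply(num, function(f) {
    v <- out[[f]]
    !is.na(v) && (!is.numeric(v) || v < 0 || !is.finite(v))
  }, logical(1))]
  if (length(bad))
    stop("numeric snapshot field(s) must be finite and non-negative: ",
         paste(bad, collapse = ", "))
  df <- as.data.frame(out[names(fields)], stringsAsFactors = FALSE)
  class(df) <- c("patient_snapshot", "data.frame")
  df
}

#' Load a guideline rule set from a declarative YAML file
#'
#' A rule set names a therapy and time window and lists indication and
#' contraindication rules. Each rule has an `id`, `kind`
#' (`indication`/`contraindication`), `description` and either a single
#' predicate (`field`, `op` in `lt,le,gt,ge,eq,flag`, `threshold`, `units`) or
#' an `any_of` list of such clauses (logical OR). Predicates may reference
#' only the fields in [snapshot_fields()]. The bundled rt-PA intravenous 3-h
#' set is available via [builtin_ruleset()].
#'
#' @param source Path to a YAML rule-set file.
#' @return An object of class `ppm_ruleset`.
#' @export
load_ruleset <- function(source) {
  raw <- yaml::read_yaml(source)
  ruleset_from_list(raw)
}

#' Build a rule set from an R list
#'
#' Same structure as the YAML file; see [load_ruleset()].
#' @param raw Named list with `name`, `therapy`, `time_window`, `rules`.
#' @return A `ppm_ruleset`.
#' @export
ruleset_from_list <- function(raw) {
  for (k in c("name", "therapy", "rules"))
    if (is.null(raw[[k]])) stop("rule set lacks required entry '", k, "'")
  ids <- vapply(raw$rules, function(r) as.character(r$id %||% ""), character(1))
  if (any(!nzchar(ids))) stop("every rule needs an id")
  if (anyDuplicated(ids))
    stop("duplicate rule id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  kinds <- vapply(raw$rules, function(r) as.character(r$kind %||% ""), character(1))
  if (!all(kinds %in% c("indication", "contraindication")))
    stop("rule kind must be 'indication' or 'contraindication'")
  if (!any(kinds == "indication")) stop("rule set must contain at least one indication")
  known <- names(snapshot_fields())
  for (r in raw$rules) {
    clauses <- r$any_of %||% list(r)
    for (cl in clauses) {
      if (is.null(cl$field) || is.null(cl$op))
        stop("rule '", r$id, "' has a clause without field/op")
      if (!cl$field %in% known)
        stop("rule '", r$id, "' references unknown field '", cl$field, "'")
      if (!cl$op %in% c("lt", "le", "gt", "ge", "eq", "flag"))
        stop("rule '", r$id, "' uses unknown op '", cl$op, "'")
      if (cl$op != "flag" && !is_scalar_number(cl$threshold))
        stop("rule '", r$id, "' needs a numeric threshold for op '", cl$op, "'")
    }
  }
  structure(raw, class = "ppm_ruleset")
}

#' Serialize a rule set back to YAML
#'
#' Inverse of [load_ruleset()]: parsing the written file reproduces the rule
#' set structurally.
#' @param ruleset A `ppm_ruleset`.
#' @param dest Destination file path.
#' @export
write_ruleset <- function(ruleset, dest) {
  yaml::write_yaml(unclass(ruleset), dest)
  invisible(NULL)
}

#' Load a rule set bundled with the package
#'
#' @param name Rule-set name; currently `"rtpa_iv_3h"`, the intravenous rt-PA
#'   eligibility criteria for the 3-hour window (4 indications, 17
#'   contraindications). Arterial-thrombolysis rule sets are supported as
#'   user-supplied files only.
#' @return A `ppm_ruleset`.
#' @export
builtin_ruleset <- function(name = "rtpa_iv_3h") {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "strokeppm")
  if (!nzchar(path)) stop("no built-in rule set named '", name, "'")
  load_ruleset(path)
}

#' @export
print.ppm_ruleset <- function(x, ...) {
  kinds <- vapply(x$rules, function(r) r$kind, character(1))
  cat(sprintf("<rule set %s (%s, %g h window): %d indications, %d contraindications>\n",
              x$name, x$therapy, x$time_window %||% NA_real_,
              sum(kinds == "indication"), sum(kinds == "contraindication")))
  invisible(x)
}

# Evaluate one clause over a snapshot data frame -> logical vector (NA = missing)
.eval_clause <- function(snapshots, clause) {
  v <- snapshots[[clause$field]]
  if (is.null(v)) v <- rep(NA, nrow(snapshots))
  switch(clause$op,
         flag = as.logical(v),
         lt = v < clause$threshold,
         le = v <= clause$threshold,
         gt = v > clause$threshold,
         ge = v >= clause$threshold,
         eq = v == clause$threshold,
         stop("unknown op '", clause$op, "'"))
}

# Evaluate one rule (possibly any_of) -> logical vector; TRUE|NA gives TRUE
.eval_rule <- function(snapshots, rule) {
  clauses <- rule$any_of %||% list(rule)
  out <- rep(FALSE, nrow(snapshots))
  for (cl in clauses) out <- out | .eval_clause(snapshots, cl)
  out
}

.rule_fields <- function(rule) {
  vapply(rule$any_of %||% list(rule), function(cl) cl$field, character(1))
}

# Full rule evaluation over a cohort. Returns hold matrix (n x rules, NA =
# undecidable from available fields) and per-rule missing-field matrix.
.evaluate_matrix <- function(snapshots, ruleset) {
  n <- nrow(snapshots)
  ids <- vapply(ruleset$rules, function(r) r$id, character(1))
  hold <- matrix(NA, n, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ruleset$rules))
    hold[, j] <- .eval_rule(snapshots, ruleset$rules[[j]])
  kinds <- vapply(ruleset$rules, function(r) r$kind, character(1))
  list(hold = hold, ids = ids, kinds = kinds)
}

#' Evaluate a rule set against one patient snapshot
#'
#' Every rule is evaluated (no short-circuiting), so the explanation is
#' complete: all satisfied indications and all violated contraindications are
#' reported. The therapy is recommended iff every indication holds, no
#' contraindication holds and — under the default `"strict"` policy — no
#' referenced field is missing. Under `"permissive"`, rules undecidable
#' because of missing fields are treated as non-violated/unsatisfied but do
#' not by themselves block a recommendation unless they are indications.
#'
#' @param patient A [patient_snapshot()] (or one-row data frame / named list
#'   with snapshot fields).
#' @param ruleset A `ppm_ruleset`.
#' @param missing_policy `"strict"` (default) or `"permissive"`.
#' @return An object of class `ppm_recommendation` with elements `recommend`,
#'   `satisfied_indications`, `violated_contraindications`, `missing_fields`.
#' @export
evaluate_rules <- function(patient, ruleset,
                           missing_policy = c("strict", "permissive")) {
  missing_policy <- match.arg(missing_policy)
  if (!is.data.frame(patient)) patient <- as.data.frame(patient, stringsAsFactors = FALSE)
  if (nrow(patient) != 1L) stop("evaluate_rules takes a single snapshot; see recommend_cohort")
  m <- .evaluate_matrix(patient, ruleset)
  hold <- m$hold[1, ]
  ind <- m$kinds == "indication"
  missing_fields <- character(0)
  for (j in which(is.na(hold))) {
    for (f in .rule_fields(ruleset$rules[[j]]))
      if (!f %in% names(patient) || is.na(patient[[f]][1]))
        missing_fields <- c(missing_fields, f)
  }
  missing_fields <- unique(missing_fields)
  satisfied <- m$ids[ind & !is.na(hold) & hold]
  violated <- m$ids[!ind & !is.na(hold) & hold]
  all_ind_ok <- all(hold[ind] %in% TRUE)
  no_contra <- !any(hold[!ind] %in% TRUE)
  recommend <- all_ind_ok && no_contra &&
    (missing_policy == "permissive" || length(missing_fields) == 0L)
  structure(list(recommend = recommend,
                 satisfied_indications = satisfied,
                 violated_contraindications = violated,
                 missing_fields = missing_fields),
            class = "ppm_recommendation")
}

#' @export
print.ppm_recommendation <- function(x, ...) {
  cat(sprintf("<recommendation: %s>\n", if (x$recommend) "THROMBOLYSIS RECOMMENDED" else "not recommended"))
  cat("  satisfied indications:      ", paste(x$satisfied_indications, collapse = ", "), "\n")
  cat("  violated contraindications: ", paste(x$violated_contraindications, collapse = ", "), "\n")
  if (length(x$missing_fields))
    cat("  missing fields:             ", paste(x$missing_fields, collapse = ", "), "\n")
  invisible(x)
}

#' Vectorized recommendation over a cohort
#'
#' @param snapshots Data frame of patient snapshots (one row per case).
#' @param ruleset A `ppm_ruleset`.
#' @param missing_policy See [evaluate_rules()].
#' @return Logical vector: is thrombolysis recommended for each case?
#' @export
recommend_cohort <- function(snapshots, ruleset,
                             missing_policy = c("strict", "permissive")) {
  missing_policy <- match.arg(missing_policy)
  m <- .evaluate_matrix(snapshots, ruleset)
  ind <- m$kinds == "indication"
  hold_ind <- m$hold[, ind, drop = FALSE]
  hold_con <- m$hold[, !ind, drop = FALSE]
  ind_ok <- rowSums(!is.na(hold_ind) & hold_ind) == ncol(hold_ind)
  contra <- rowSums(!is.na(hold_con) & hold_con) > 0
  rec <- ind_ok & !contra
  if (missing_policy == "strict") {
    any_missing <- rowSums(is.na(m$hold)) > 0
    rec <- rec & !any_missing
  }
  rec
}

#' Conformance quadrant of recommendation vs. actual treatment
#'
#' Crosses the guideline recommendation with the treatment actually given:
#' `A` recommended and treated, `B` not recommended but treated, `C`
#' recommended but not treated, `D` neither. `A` and `D` follow the
#' guideline; `B` and `C` do not.
#'
#' @param recommendation A `ppm_recommendation`, or a logical vector of
#'   recommendations.
#' @param treated Logical (vector): was thrombolysis actually performed?
#' @return Factor with levels `A`, `B`, `C`, `D`.
#' @export
label_conformance <- function(recommendation, treated) {
  rec <- if (inherits(recommendation, "ppm_recommendation"))
    recommendation$recommend else as.logical(recommendation)
  treated <- as.logical(treated)
  q <- ifelse(rec & treated, "A",
              ifelse(!rec & treated, "B",
                     ifelse(rec & !treated, "C", "D")))
  factor(q, levels = c("A", "B", "C", "D"))
}

#' Summarize cohort conformance
#'
#' Counts the quadrants and reports the nonconformance percentage
#' `100 * (B + C) / total`, rounded half-up to one decimal (so 151 of 1191
#' nonconforming cases reports 12.7).
#'
#' @param labels Factor/character vector of quadrant labels `A`-`D`.
#' @return List with `counts` (named A/B/C/D), `n`, `nonconformance_pct`.
#' @export
summarize_conformance <- function(labels) {
  if (!length(labels)) stop("cannot summarize an empty label set")
  labels <- factor(as.character(labels), levels = c("A", "B", "C", "D"))
  if (anyNA(labels)) stop("labels must be quadrants A, B, C or D")
  counts <- table(labels)
  n <- length(labels)
  pct <- floor(1000 * (counts[["B"]] + counts[["C"]]) / n + 0.5) / 10
  list(counts = c(counts), n = n, nonconformance_pct = pct)
}
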