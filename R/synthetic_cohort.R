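#' Default class-conditional activity occurrence probabilities
#'
#' Occurrence probability of each acute-period activity, conditional on the
#' actual treatment label, for the intravenous-thrombolysis cohort: the four
#' clinically selected activities use the reference cohort's occurrence
#' fractions (treated denominators 128, untreated 918); the three placeholder
#' activities (admission, CT scan, blood draw) complete the 7-activity
#' control flow with class-independent rates.
#'
#' @return Data frame with columns `activity`, `p_treated`, `p_untreated`, in
#'   fixed clinical order.
#' @export
default_activity_emission <- function() {
  data.frame(
    activity = c("admission", "ct_scan", "blood_draw", "MRA",
                 "coagulation_test", "anti_platelet", "statin"),
    p_treated = c(1, 0.8, 0.7, 7 / 128, 44 / 128, 8 / 128, 10 / 128),
    p_untreated = c(1, 0.8, 0.7, 204 / 918, 746 / 918, 396 / 918, 177 / 918),
    stringsAsFactors = FALSE)
}

#' Synthetic-cohort configuration
#'
#' Defines the generating conditions of a synthetic stroke cohort: cohort
#' size, target treated fraction (default 273/1191, the reference cohort's
#' intravenous-thrombolysis prevalence), guideline-nonconformance rate
#' (default 0.126), how treatment labels are decided, and the distributions
#' of the patient measurements. The default numeric marginals are calibrated
#' so that the guideline recommendation probability matches the treated
#' fraction (see the package vignette); they are invented — no empirical
#' distributions are available for the reference cohort — and fully overridable.
#'
#' @param n_cases Number of cases.
#' @param therapy Outcome label name (default `"iv_thrombolysis"`).
#' @param treated_fraction Target treated prevalence.
#' @param nonconformance_rate Fraction of cases whose treatment is flipped
#'   against the guideline recommendation (quadrants B and C).
#' @param b_flip_fraction Share of flips that create quadrant-B cases
#'   (treated against a negative recommendation); the rest create C cases.
#' @param decision_model `"guideline_faithful"` (treatment = recommendation
#'   plus flips), `"feature_logistic"` (logistic in severity/urgency
#'   features) or `"label_noise"` (labels independent of features).
#' @param ruleset The rule set shared by generator and engine (default the
#'   built-in rt-PA 3-h set).
#' @param numeric_params Named list of distribution parameters (see
#'   defaults in the function body / vignette).
#' @param flag_prevalence Named probabilities for the boolean snapshot flags.
#' @param activity_emission Data frame as [default_activity_emission()].
#' @param seed Integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 1191L, therapy = "iv_thrombolysis",
                          treated_fraction = 273 / 1191,
                          nonconformance_rate = 0.126,
                          b_flip_fraction = 0.5,
                          decision_model = c("guideline_faithful",
                                             "feature_logistic", "label_noise"),
                          ruleset = NULL,
                          numeric_params = list(),
                          flag_prevalence = c(),
                          activity_emission = default_activity_emission(),
                          seed = 1L) {
  decision_model <- match.arg(decision_model)
  if (treated_fraction <= 0 || treated_fraction >= 1)
    stop("treated_fraction must be in (0, 1)")
  if (nonconformance_rate < 0 || nonconformance_rate >= 1)
    stop("nonconformance_rate must be in [0, 1)")
  np <- list(
    age = list(mean = 68, sd = 12, lo = 18, hi = 95),
    otc = list(meanlog = log(4.5), sdlog = 0.8, hi = 24),
    glucose = list(meanlog = log(6), sdlog = 0.25),
    platelet = list(mean = 220, sd = 60, lo = 20, hi = 600),
    bp = list(mean_sys = 140, sd_sys = 20, mean_dia = 80, sd_dia = 10, cor = 0.6),
    fast = list(size = 9, prob = 0.45),
    inr = list(mean = 1.05, sd = 0.15, lo = 0.5, hi = 3),
    pt = list(mean = 12, sd = 1.5, lo = 8, hi = 20),
    glucose_lab_noise_sd = 0.3)
  np[names(numeric_params)] <- numeric_params
  fp <- c(ischemic_deficit = 0.95, consent_signed = 0.97,
          intracranial_hemorrhage = 0.01, history_ich = 0.01,
          stroke_or_head_injury_3mo = 0.01,
          intracranial_neoplasm_or_aneurysm = 0.01,
          intracranial_spinal_surgery_3mo = 0.01, major_surgery_2wk = 0.01,
          gi_or_urinary_bleed_3wk = 0.01, active_visceral_hemorrhage = 0.01,
          aortic_arch_dissection = 0.01,
          recent_difficult_arterial_puncture_1wk = 0.01, lmwh_24h = 0.01,
          thrombin_or_xa_inhibitor_48h = 0.01, abnormal_lab = 0.01,
          large_infarct_area = 0.01)
  fp[names(flag_prevalence)] <- flag_prevalence
  if (any(fp < 0 | fp > 1)) stop("flag prevalences must lie in [0, 1]")
  if (any(activity_emission$p_treated < 0 | activity_emission$p_treated > 1 |
          activity_emission$p_untreated < 0 | activity_emission$p_untreated > 1))
    stop("activity emission probabilities must lie in [0, 1]")
  if (!is.null(np$platelet$lo) && np$platelet$lo <= 0)
    stop("platelet distribution admits non-positive counts")
  structure(list(n_cases = as.integer(n_cases), therapy = therapy,
                 treated_fraction = treated_fraction,
                 nonconformance_rate = nonconformance_rate,
                 b_flip_fraction = b_flip_fraction,
                 decision_model = decision_model,
                 ruleset = ruleset,
                 numeric_params = np, flag_prevalence = fp,
                 activity_emission = activity_emission,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

.rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

.rtrunclnorm <- function(n, meanlog, sdlog, hi = Inf) {
  u <- stats::runif(n, 0, stats::plnorm(hi, meanlog, sdlog))
  stats::qlnorm(u, meanlog, sdlog)
}

.draw_snapshots <- function(n, np, fp) {
  bp_z <- stats::rnorm(n)
  sys <- np$bp$mean_sys + np$bp$sd_sys * bp_z
  dia <- np$bp$mean_dia + np$bp$sd_dia *
    (np$bp$cor * bp_z + sqrt(1 - np$bp$cor^2) * stats::rnorm(n))
  df <- data.frame(
    age = round(.rtruncnorm(n, np$age$mean, np$age$sd, np$age$lo, np$age$hi)),
    onset_to_consult = round(.rtrunclnorm(n, np$otc$meanlog, np$otc$sdlog,
                                          np$otc$hi), 2),
    glucose = round(stats::rlnorm(n, np$glucose$meanlog, np$glucose$sdlog), 2),
    platelet_count = round(.rtruncnorm(n, np$platelet$mean, np$platelet$sd,
                                       np$platelet$lo, np$platelet$hi)),
    systolic_bp = round(pmax(sys, 70)),
    diastolic_bp = round(pmax(dia, 40)),
    inr = round(.rtruncnorm(n, np$inr$mean, np$inr$sd, np$inr$lo, np$inr$hi), 2),
    pt = round(.rtruncnorm(n, np$pt$mean, np$pt$sd, np$pt$lo, np$pt$hi), 1),
    neuro_deficit_score = stats::rbinom(n, np$fast$size, np$fast$prob))
  for (f in names(fp)) df[[f]] <- stats::runif(n) < fp[[f]]
  df
}

#' Generate a labelled synthetic stroke cohort
#'
#' For each case a patient snapshot is drawn from the configured
#' distributions; the guideline recommendation is computed with the shared
#' rule engine; the treatment label is set by the decision model (by default
#' equal to the recommendation, then a fraction `nonconformance_rate` of
#' cases is flipped against it, split between B- and C-type flips); and the
#' event trace is emitted with each activity occurring with its
#' class-conditional probability, in fixed clinical order, at
#' minute-resolution timestamps inside a 24-h admission window. The
#' coagulation-test event carries a laboratory blood-glucose payload
#' (`glucose_lab`). Bit-identical for a given seed.
#'
#' @param config A [cohort_config()].
#' @return Object of class `ppm_cohort`: list with `log` (`ppm_event_log`),
#'   `snapshots` (data frame, `case_id` first), `recommended`, `treated`
#'   (logical vectors), `quadrant` (conformance factor) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n_cases
  ruleset <- config$ruleset %||% builtin_ruleset("rtpa_iv_3h")
  snaps <- .draw_snapshots(n, config$numeric_params, config$flag_prevalence)
  rec <- recommend_cohort(snaps, ruleset)

  treated <- switch(config$decision_model,
    guideline_faithful = {
      tr <- rec
      n_flip <- round(config$nonconformance_rate * n)
      n_b <- round(config$b_flip_fraction * n_flip)
      n_c <- n_flip - n_b
      pool_b <- which(!rec); pool_c <- which(rec)
      if (length(pool_b) < n_b || length(pool_c) < n_c)
        stop("cohort too small for the requested nonconformance flips")
      if (n_b > 0) tr[sample(pool_b, n_b)] <- TRUE
      if (n_c > 0) tr[sample(pool_c, n_c)] <- FALSE
      tr
    },
    feature_logistic = {
      z <- function(v) (v - mean(v)) / stats::sd(v)
      lp <- stats::qlogis(config$treated_fraction) -
        2.0 * z(snaps$onset_to_consult) + 1.5 * z(snaps$neuro_deficit_score) -
        0.5 * z(snaps$age)
      stats::runif(n) < stats::plogis(lp)
    },
    label_noise = stats::runif(n) < config$treated_fraction)

  em <- config$activity_emission
  epoch <- as.POSIXct("2020-03-01 08:00:00", tz = "UTC")
  lab_sd <- config$numeric_params$glucose_lab_noise_sd
  case_ids <- sprintf("case%04d", seq_len(n))
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    p <- if (treated[i]) em$p_treated else em$p_untreated
    occurs <- stats::runif(nrow(em)) < p
    acts <- em$activity[occurs]
    gaps <- round(stats::runif(length(acts), 10, 180))
    times <- epoch + 60 * cumsum(gaps)
    payload <- NULL
    if (length(acts)) {
      payload <- data.frame(glucose_lab = rep(NA_real_, length(acts)))
      coag <- which(acts == "coagulation_test")
      if (length(coag))
        payload$glucose_lab[coag] <-
          pmax(round(snaps$glucose[i] + stats::rnorm(1, 0, lab_sd), 1), 0.5)
    }
    labels <- stats::setNames(list(treated[i]), config$therapy)
    traces[[i]] <- trace(case_ids[i], acts, times, payload = payload,
                         case_attributes = as.list(snaps[i, , drop = FALSE]),
                         labels = labels)
  }
  log <- event_log(traces, alphabet = em$activity)
  structure(list(log = log,
                 snapshots = cbind(data.frame(case_id = case_ids,
                                              stringsAsFactors = FALSE), snaps),
                 recommended = rec, treated = treated,
                 quadrant = label_conformance(rec, treated),
                 config = config),
            class = "ppm_cohort")
}

#' @export
print.ppm_cohort <- function(x, ...) {
  s <- summarize_conformance(x$quadrant)
  cat(sprintf("<synthetic cohort: %d cases, %d treated, nonconformance %.1f%% (A=%d B=%d C=%d D=%d)>\n",
              length(x$treated), sum(x$treated), s$nonconformance_pct,
              s$counts[["A"]], s$counts[["B"]], s$counts[["C"]], s$counts[["D"]]))
  invisible(x)
}

#' The two-trace worked encoding example
#'
#' A fixture of two traces t1 = A,B,C,D,B and t2 = A,C,D,E over the alphabet
#' A,B,C,D,E, where the two occurrences of B in t1 carry blood-glucose
#' payloads 5.1 and then 8.3 — so frequency encoding gives `c(1,2,1,1,0)` and
#' `c(1,0,1,1,1)`, and last-state encoding of (B, blood_glucose) gives 8.3.
#'
#' @return A `ppm_event_log` with two traces.
#' @export
generate_worked_example_log <- function() {
  t1 <- trace("t1", c("A", "B", "C", "D", "B"),
              payload = data.frame(blood_glucose = c(NA, 5.1, NA, NA, 8.3)))
  t2 <- trace("t2", c("A", "C", "D", "E"))
  event_log(list(t1, t2))
}

#' Default encoding configuration for a generated cohort
#'
#' Control-flow frequencies over the cohort alphabet, every snapshot field as
#' a static case attribute, and the last-state laboratory glucose carried by
#' the coagulation-test event.
#'
#' @param log A cohort's `ppm_event_log` (for its alphabet).
#' @param use_control_flow Include the control-flow block? Default `TRUE`.
#' @return An [encoding_config()].
#' @export
default_encoding_config <- function(log, use_control_flow = TRUE) {
  encoding_config(alphabet = log$alphabet,
                  case_attributes = names(snapshot_fields()),
                  event_attributes = list(c("coagulation_test", "glucose_lab")),
                  use_control_flow = use_control_flow)
}

#' Flip a fixed fraction of labels
#'
#' Flips exactly `round(rate * n)` labels, chosen uniformly without
#' replacement; reproducible for a given seed. Supports robustness
#' experiments on label quality.
#'
#' @param labels Logical vector.
#' @param rate Flip rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return Logical vector with flips applied.
#' @export
inject_label_noise <- function(labels, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  labels <- as.logical(labels)
  n_flip <- round(rate * length(labels))
  if (n_flip == 0L) return(labels)
  set.seed(seed)
  idx <- sample(length(labels), n_flip)
  labels[idx] <- !labels[idx]
  labels
}
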