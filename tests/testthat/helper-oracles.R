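# Independent oracles, written as direct transcriptions so they stay
# structurally unrelated to the implementations they check.

# Eligibility criteria for intravenous rt-PA within 3 h, as one nested
# conditional per eligibility criterion.
oracle_recommend <- function(p) {
  if (!isTRUE(p$ischemic_deficit)) return(FALSE)            # indication 1
  if (!(p$onset_to_consult <= 3)) return(FALSE)             # indication 2
  if (!(p$age > 18)) return(FALSE)                          # indication 3
  if (!isTRUE(p$consent_signed)) return(FALSE)              # indication 4
  if (isTRUE(p$intracranial_hemorrhage)) return(FALSE)      # contra 1
  if (isTRUE(p$history_ich)) return(FALSE)                  # contra 2
  if (isTRUE(p$stroke_or_head_injury_3mo)) return(FALSE)    # contra 3
  if (isTRUE(p$intracranial_neoplasm_or_aneurysm)) return(FALSE) # contra 4
  if (isTRUE(p$intracranial_spinal_surgery_3mo)) return(FALSE)   # contra 5
  if (isTRUE(p$major_surgery_2wk)) return(FALSE)            # contra 6
  if (isTRUE(p$gi_or_urinary_bleed_3wk)) return(FALSE)      # contra 7
  if (isTRUE(p$active_visceral_hemorrhage)) return(FALSE)   # contra 8
  if (isTRUE(p$aortic_arch_dissection)) return(FALSE)       # contra 9
  if (isTRUE(p$recent_difficult_arterial_puncture_1wk)) return(FALSE) # contra 10
  if (p$systolic_bp > 180 || p$diastolic_bp > 100) return(FALSE)      # contra 11
  if (p$platelet_count < 100) return(FALSE)                 # contra 12
  if (isTRUE(p$lmwh_24h)) return(FALSE)                     # contra 13
  if (p$inr > 1.7 || p$pt > 15) return(FALSE)               # contra 14
  if (isTRUE(p$thrombin_or_xa_inhibitor_48h) || isTRUE(p$abnormal_lab))
    return(FALSE)                                           # contra 15
  if (p$glucose < 2.8 || p$glucose > 22.22) return(FALSE)   # contra 16
  if (isTRUE(p$large_infarct_area)) return(FALSE)           # contra 17
  TRUE
}

# Random snapshots spanning every rule threshold on both sides.
random_snapshots <- function(n, seed) {
  set.seed(seed)
  df <- data.frame(
    age = round(runif(n, 16, 95), 1),
    onset_to_consult = round(runif(n, 0, 5), 2),
    glucose = round(runif(n, 2, 25), 2),
    platelet_count = round(runif(n, 80, 400)),
    systolic_bp = round(runif(n, 120, 200)),
    diastolic_bp = round(runif(n, 60, 110)),
    inr = round(runif(n, 0.8, 2.0), 2),
    pt = round(runif(n, 9, 17), 1),
    neuro_deficit_score = sample(0:9, n, replace = TRUE))
  fields <- snapshot_fields()
  for (f in names(fields)[fields == "flag"]) {
    prob <- if (f %in% c("ischemic_deficit", "consent_signed")) 0.95 else 0.03
    df[[f]] <- runif(n) < prob
  }
  df
}

# All-pairs concordance AUC with half-credit for ties.
auc_bruteforce <- function(truth, scores) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  s <- 0
  for (a in pos) s <- s + sum(a > neg) + 0.5 * sum(a == neg)
  s / (length(pos) * length(neg))
}

# Random linearly separable two-feature set.
separable_toy <- function(n = 60, seed = 7) {
  set.seed(seed)
  x <- cbind(a = runif(n), b = runif(n))
  y <- x[, "a"] + x[, "b"] > 1
  list(x = x, y = y)
}
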