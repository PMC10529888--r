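#' T1 reduction rate after gadoxetic acid
#'
#' `RR = (T1plain - T1HBP) / T1plain * 100%`: the percent shortening of
#' the T1 relaxation time between the plain map and the hepatobiliary
#' phase, a surrogate of hepatocellular contrast uptake and hence of
#' hepatocyte function. A hepatobiliary T1 above the plain T1 (possible
#' with contrast-timing failure) yields a negative rate; it is flagged
#' with a warning but not rejected.
#'
#' @param t1_plain Plain T1 relaxation time, ms (> 0, vectorised).
#' @param t1_hbp Hepatobiliary-phase T1 relaxation time, ms (> 0).
#' @return Reduction rate in percent.
#' @examples
#' reduction_rate(800, 200)   # 75
#' reduction_rate(751.9, 310.2)
#' @export
reduction_rate <- function(t1_plain, t1_hbp) {
  if (!is.numeric(t1_plain) || anyNA(t1_plain) || any(!is.finite(t1_plain)) ||
      any(t1_plain <= 0)) {
    abort("`t1_plain` must be finite and strictly positive.")
  }
  if (!is.numeric(t1_hbp) || anyNA(t1_hbp) || any(!is.finite(t1_hbp)) ||
      any(t1_hbp <= 0)) {
    abort("`t1_hbp` must be finite and strictly positive.")
  }
  if (length(t1_plain) != length(t1_hbp)) {
    abort("`t1_plain` and `t1_hbp` must have equal length.")
  }
  if (any(t1_hbp > t1_plain)) {
    warn("Some hepatobiliary T1 values exceed the plain T1; reduction rate is negative for those records.")
  }
  (t1_plain - t1_hbp) / t1_plain * 100
}

#' Volume-assisted liver-function estimate
#'
#' `scale * exp(rr_coeff * rr) * exp(vol_coeff * volume / vol_unit_ml)`,
#' on the scale of the ICG plasma disappearance rate (%/min). Supplying
#' the total liver volume gives the estimated liver function (eLF);
#' supplying the remnant volume after the planned resection gives the
#' estimated remnant liver function (erLF). The estimate is strictly
#' increasing in both the reduction rate and the volume, so erLF never
#' exceeds eLF for the same patient.
#'
#' @param rr T1 reduction rate, percent (vectorised).
#' @param volume_ml Liver (or remnant) volume, mL, >= 0.
#' @param coefficients A [model_coefficients()].
#' @return Function estimate in %/min equivalents.
#' @examples
#' estimated_function(rr = 58.4, volume_ml = 1609)  # eLF
#' estimated_function(rr = 58.4, volume_ml = 1176)  # erLF after resection
#' @export
estimated_function <- function(rr, volume_ml, coefficients = model_coefficients()) {
  if (!is.numeric(rr) || anyNA(rr) || any(!is.finite(rr))) {
    abort("`rr` must be finite.")
  }
  check_number(volume_ml, "volume_ml", min = 0, allow_vector = TRUE)
  if (length(rr) != length(volume_ml) && length(rr) != 1 && length(volume_ml) != 1) {
    abort("`rr` and `volume_ml` must have compatible lengths.")
  }
  coefficients$scale *
    exp(coefficients$rr_coeff * rr) *
    exp(coefficients$vol_coeff * volume_ml / coefficients$vol_unit_ml)
}

#' Classify estimated remnant liver function
#'
#' Applies the postoperative ICG partition to the erLF score: dysfunction
#' predicted below 10, normal function above 17, at risk in between
#' (closed interval), using the same rule object as [classify_postop()]
#' so the two classifications can never drift apart.
#'
#' @param erlf Estimated remnant liver function, %/min equivalents (>= 0).
#' @inheritParams classify_postop
#' @return Factor with levels `PNLF`, `at_risk`, `PLDF`.
#' @export
classify_erlf <- function(erlf, rule = icg_class_rule()) {
  classify_postop(erlf, rule = rule)
}

#' Bilirubin unit conversion
#'
#' Converts umol/L to mg/dL via the molar mass of bilirubin
#' (584.66 g/mol): `mg/dL = umol/L * 584.66 * 1e-4`. 50 umol/L (the 50/50
#' failure threshold) converts to 2.92 mg/dL.
#'
#' @param value_umol_l Bilirubin concentration in umol/L (vectorised, >= 0).
#' @param rule An [outcome_rule()] carrying the molar mass.
#' @return Concentration in mg/dL.
#' @examples
#' convert_bilirubin(50)
#' @export
convert_bilirubin <- function(value_umol_l, rule = outcome_rule()) {
  check_number(value_umol_l, "value_umol_l", min = 0, allow_vector = TRUE)
  value_umol_l * rule$bilirubin_molar_mass_g_mol * 1e-4
}

#' Postoperative clinical outcome flags
#'
#' Evaluates the bilirubin/INR course of one patient over the
#' postoperative window (days 3-7 by default). Acute dysfunction: on any
#' day in the window, bilirubin exceeds 1.0 mg/dL *and* its preoperative
#' value, or INR exceeds 1.15 *and* its preoperative value (the rise
#' above baseline is required so that a chronically elevated but stable
#' lab does not trigger the flag). Severe failure: the 50/50 criterion
#' (bilirubin > 2.92 mg/dL together with INR > 1.7 on the same day) or a
#' peak bilirubin above 7 mg/dL. Severe failure implies acute
#' dysfunction by construction.
#'
#' @param preop_bili Preoperative bilirubin, mg/dL.
#' @param bili_series Data frame with columns `pod` (postoperative day,
#'   1-90) and `value` (mg/dL, > 0).
#' @param preop_inr Preoperative INR.
#' @param inr_series Data frame with columns `pod` and `value`.
#' @param rule An [outcome_rule()].
#' @return One-row tibble with logical columns `acute_dysfunction` and
#'   `severe_failure`.
#' @examples
#' clinical_outcome(
#'   preop_bili = 0.6,
#'   bili_series = data.frame(pod = 3:7, value = c(1.2, 2.0, 3.0, 2.5, 1.8)),
#'   preop_inr = 1.0,
#'   inr_series = data.frame(pod = 3:7, value = c(1.2, 1.5, 1.8, 1.6, 1.3))
#' )
#' @export
clinical_outcome <- function(preop_bili, bili_series, preop_inr, inr_series,
                             rule = outcome_rule()) {
  check_number(preop_bili, "preop_bili", min = 0)
  check_number(preop_inr, "preop_inr", min = 0)
  bili <- check_lab_series(bili_series, "bili_series")
  inr <- check_lab_series(inr_series, "inr_series")

  window <- rule$window_days
  b <- dplyr::filter(bili, .data$pod %in% window)
  i <- dplyr::filter(inr, .data$pod %in% window)
  if (nrow(b) == 0 && nrow(i) == 0) {
    warn("No lab values fall in the postoperative window; flags computed on an empty series.")
  }

  bili_up <- b$value > rule$bili_dysfunction_mg_dl & b$value > preop_bili
  inr_up <- i$value > rule$inr_dysfunction & i$value > preop_inr
  acute <- any(bili_up) || any(inr_up)

  fifty_bili_mg_dl <- convert_bilirubin(rule$fifty_fifty_bili_umol_l, rule)
  paired <- dplyr::inner_join(b, i, by = "pod", suffix = c("_bili", "_inr"))
  fifty_fifty <- any(paired$value_bili > fifty_bili_mg_dl &
                       paired$value_inr > rule$fifty_fifty_inr)
  severe <- fifty_fifty || any(b$value > rule$severe_bili_mg_dl)

  tibble::tibble(acute_dysfunction = acute || severe,
                 severe_failure = severe)
}

check_lab_series <- function(series, name) {
  if (!is.data.frame(series) || !all(c("pod", "value") %in% names(series))) {
    abort(sprintf("`%s` must be a data frame with columns pod and value.", name))
  }
  if (nrow(series) > 0) {
    check_number(series$pod, paste0(name, "$pod"), min = 1, max = 90,
                 allow_vector = TRUE)
    if (any(series$value <= 0) || anyNA(series$value)) {
      abort(sprintf("`%s$value` must be strictly positive.", name))
    }
  }
  tibble::as_tibble(series[c("pod", "value")])
}

#' Score a cohort with the volume-assisted function model
#'
#' Adds the derived per-patient columns to a cohort table: the reduction
#' rate `rr` from the T1 pair, the remnant volume `rlv_ml = lv_ml -
#' resected_ml`, the function estimates `elf` (total volume) and `erlf`
#' (remnant volume), and the three classifications `preop_class` (ICG,
#' NLF/LDF), `postop_class` (ICG reference, PNLF/at_risk/PLDF) and
#' `erlf_class` (model prediction, same partition). All derived columns
#' are recomputable from the raw fields, so re-scoring a scored cohort is
#' idempotent.
#'
#' @param cohort Cohort tibble with columns `t1_plain`, `t1_hbp`,
#'   `lv_ml`, `resected_ml`, `pdr_pre`, `r15_pre`, `pdr_post`.
#' @param coefficients A [model_coefficients()].
#' @param rule An [icg_class_rule()].
#' @return The cohort with derived columns appended.
#' @export
score_cohort <- function(cohort, coefficients = model_coefficients(),
                         rule = icg_class_rule()) {
  needed <- c("t1_plain", "t1_hbp", "lv_ml", "resected_ml",
              "pdr_pre", "r15_pre", "pdr_post")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("Cohort is missing required columns: ",
                 paste(missing, collapse = ", "), "."))
  }
  if (any(cohort$resected_ml > cohort$lv_ml)) {
    abort("`resected_ml` exceeds `lv_ml` for some records.")
  }
  dplyr::mutate(
    tibble::as_tibble(cohort),
    rr = reduction_rate(.data$t1_plain, .data$t1_hbp),
    rlv_ml = .data$lv_ml - .data$resected_ml,
    elf = estimated_function(.data$rr, .data$lv_ml, coefficients),
    erlf = estimated_function(.data$rr, .data$rlv_ml, coefficients),
    preop_class = classify_preop(.data$pdr_pre, .data$r15_pre, rule),
    postop_class = classify_postop(.data$pdr_post, rule),
    erlf_class = classify_erlf(.data$erlf, rule)
  )
}
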