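#' Coefficients of the volume-assisted liver-function model
#'
#' The estimated liver function is
#' `scale * exp(rr_coeff * RR) * exp(vol_coeff * volume / vol_unit_ml)`,
#' where `RR` is the percent reduction of the T1 relaxation time between the
#' plain and hepatobiliary-phase maps and `volume` is the (remnant) liver
#' volume in mL. The defaults are the published coefficients of the model
#' (0.84, 0.038 per percent RR, 0.045 per volume unit). `vol_unit_ml` fixes
#' the unit of the volume coefficient: the default of 100 mL (equivalently
#' 0.00045 per mL) is the only reading under which the score lands on the
#' ICG-PDR scale (tens of %/min for a 1.6 L liver); a literal per-mL
#' exponent would produce values around `e^72`. See the package vignette.
#'
#' @param scale Multiplicative intercept, in %/min equivalents.
#' @param rr_coeff Exponential coefficient per percent reduction rate.
#' @param vol_coeff Exponential coefficient per volume unit.
#' @param vol_unit_ml Size of one volume unit in mL.
#' @return An object of class `erlf_coefficients`.
#' @examples
#' model_coefficients()
#' @export
model_coefficients <- function(scale = 0.84, rr_coeff = 0.038,
                               vol_coeff = 0.045, vol_unit_ml = 100) {
  check_number(scale, "scale", min = .Machine$double.eps)
  check_number(rr_coeff, "rr_coeff", min = .Machine$double.eps)
  check_number(vol_coeff, "vol_coeff", min = .Machine$double.eps)
  check_number(vol_unit_ml, "vol_unit_ml", min = .Machine$double.eps)
  structure(
    list(scale = scale, rr_coeff = rr_coeff, vol_coeff = vol_coeff,
         vol_unit_ml = vol_unit_ml),
    class = "erlf_coefficients"
  )
}

#' ICG-based classification cut-offs
#'
#' Preoperatively, liver dysfunction (LDF) is called when the plasma
#' disappearance rate falls below `preop_pdr_cutoff` (%/min) or the
#' 15-minute retention exceeds `preop_r15_cutoff` (%). Postoperatively
#' three classes are used: dysfunction (PLDF) strictly below
#' `postop_lower`, normal function (PNLF) strictly above `postop_upper`,
#' and "at risk" on the closed interval in between. The same partition is
#' applied to the estimated remnant liver function.
#'
#' @param preop_pdr_cutoff Preoperative PDR cut-off, %/min.
#' @param preop_r15_cutoff Preoperative R15 cut-off, percent.
#' @param postop_lower,postop_upper Postoperative PDR class bounds, %/min.
#' @return An object of class `icg_class_rule`.
#' @export
icg_class_rule <- function(preop_pdr_cutoff = 17, preop_r15_cutoff = 8,
                           postop_lower = 10, postop_upper = 17) {
  check_number(preop_pdr_cutoff, "preop_pdr_cutoff", min = 0)
  check_number(preop_r15_cutoff, "preop_r15_cutoff", min = 0)
  check_number(postop_lower, "postop_lower", min = 0)
  check_number(postop_upper, "postop_upper", min = 0)
  if (postop_lower >= postop_upper) {
    abort("`postop_lower` must be strictly below `postop_upper`.")
  }
  structure(
    list(preop_pdr_cutoff = preop_pdr_cutoff,
         preop_r15_cutoff = preop_r15_cutoff,
         postop_lower = postop_lower, postop_upper = postop_upper),
    class = "icg_class_rule"
  )
}

#' Post-hepatectomy clinical outcome thresholds
#'
#' Acute liver dysfunction is flagged when, on any postoperative day in
#' `window_days`, bilirubin exceeds `bili_dysfunction_mg_dl` (and the
#' preoperative value) or INR exceeds `inr_dysfunction` (and the
#' preoperative value). Severe failure is flagged by the 50/50 criterion
#' (bilirubin > 50 umol/L, i.e. 2.92 mg/dL, together with INR > 1.7 on the
#' same day) or a peak bilirubin above `severe_bili_mg_dl`.
#'
#' @param bili_dysfunction_mg_dl Bilirubin dysfunction threshold, mg/dL.
#' @param inr_dysfunction INR dysfunction threshold.
#' @param fifty_fifty_bili_umol_l 50/50 bilirubin threshold, umol/L.
#' @param fifty_fifty_inr 50/50 INR threshold.
#' @param severe_bili_mg_dl Peak-bilirubin failure threshold, mg/dL.
#' @param window_days Postoperative days examined (default 3 to 7).
#' @param bilirubin_molar_mass_g_mol Molar mass used for unit conversion.
#' @return An object of class `outcome_rule`.
#' @export
outcome_rule <- function(bili_dysfunction_mg_dl = 1.0, inr_dysfunction = 1.15,
                         fifty_fifty_bili_umol_l = 50, fifty_fifty_inr = 1.7,
                         severe_bili_mg_dl = 7.0, window_days = 3:7,
                         bilirubin_molar_mass_g_mol = 584.66) {
  check_number(bili_dysfunction_mg_dl, "bili_dysfunction_mg_dl", min = 0)
  check_number(inr_dysfunction, "inr_dysfunction", min = 0)
  check_number(fifty_fifty_bili_umol_l, "fifty_fifty_bili_umol_l", min = 0)
  check_number(fifty_fifty_inr, "fifty_fifty_inr", min = 0)
  check_number(severe_bili_mg_dl, "severe_bili_mg_dl", min = 0)
  check_number(bilirubin_molar_mass_g_mol, "bilirubin_molar_mass_g_mol", min = 0)
  if (length(window_days) < 1) abort("`window_days` must be non-empty.")
  check_number(window_days, "window_days", min = 1, max = 90, allow_vector = TRUE)
  structure(
    list(bili_dysfunction_mg_dl = bili_dysfunction_mg_dl,
         inr_dysfunction = inr_dysfunction,
         fifty_fifty_bili_umol_l = fifty_fifty_bili_umol_l,
         fifty_fifty_inr = fifty_fifty_inr,
         severe_bili_mg_dl = severe_bili_mg_dl,
         window_days = as.integer(window_days),
         bilirubin_molar_mass_g_mol = bilirubin_molar_mass_g_mol),
    class = "outcome_rule"
  )
}

default_resection_fractions <- function() {
  # Surgery mix of a tertiary hepatectomy cohort: atypical (wedge)
  # resections remove ~10% of the liver, segmentectomies ~20%,
  # hemihepatectomies ~50%; weights follow the 21/14/36 case mix.
  tibble::tibble(
    type = c("atypical", "segment", "hemihepatectomy"),
    fraction = c(0.10, 0.20, 0.50),
    weight = c(21, 14, 36) / 71
  )
}

#' Parameters of the synthetic hepatectomy cohort generator
#'
#' Location and scale defaults emulate the published characteristics of a
#' 71-patient resection cohort: plain T1 751.9 +/- 99.7 ms, liver volume
#' 1609 +/- 443 mL (lognormal, moment-matched), T1 reduction rate 61.3%
#' for normally functioning livers versus 51.9% under pre-existing
#' dysfunction, with 22/71 of patients dysfunctional. The survival link is
#' a hazard ratio of 0.87 per unit of estimated remnant function.
#'
#' @param n Number of patients.
#' @param t1_plain_mean,t1_plain_sd Plain T1 relaxation time, ms.
#' @param rr_mean_nlf,rr_mean_ldf,rr_sd T1 reduction rate (%) by latent
#'   liver-function status, and its common SD.
#' @param lv_mean,lv_sd Total liver volume, mL (lognormal moments).
#' @param ldf_fraction Probability of latent preoperative dysfunction.
#' @param resection_fractions Data frame with columns `type`, `fraction`
#'   (of liver volume removed, each in `[0, 1)`) and `weight` (sampling
#'   probability).
#' @param pdr_link_noise_sd SD of the noise linking ICG-PDR to the
#'   function score, %/min.
#' @param survival_log_hazard_per_erlf Log-hazard per unit of estimated
#'   remnant function (default `log(0.87)`).
#' @param baseline_hazard_per_day Baseline death hazard per day; the
#'   default gives a median survival near three years at the cohort-mean
#'   remnant function.
#' @param censor_rate Independent censoring rate per day.
#' @param admin_censor_days Administrative follow-up truncation, days.
#' @param lab_noise_sd Lognormal sd (log scale) of bilirubin/INR noise.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `generator_params`.
#' @examples
#' generator_params(n = 71, seed = 1)
#' @export
generator_params <- function(n,
                             t1_plain_mean = 751.9, t1_plain_sd = 99.7,
                             rr_mean_nlf = 61.3, rr_mean_ldf = 51.9,
                             rr_sd = 10,
                             lv_mean = 1609, lv_sd = 443,
                             ldf_fraction = 22 / 71,
                             resection_fractions = default_resection_fractions(),
                             pdr_link_noise_sd = 3,
                             survival_log_hazard_per_erlf = log(0.87),
                             baseline_hazard_per_day = 0.0049,
                             censor_rate = 5e-4,
                             admin_censor_days = 1800,
                             lab_noise_sd = 0.15,
                             seed = NULL) {
  check_number(n, "n", min = 1)
  check_number(t1_plain_mean, "t1_plain_mean", min = .Machine$double.eps)
  check_number(t1_plain_sd, "t1_plain_sd", min = 0)
  check_number(rr_mean_nlf, "rr_mean_nlf")
  check_number(rr_mean_ldf, "rr_mean_ldf")
  check_number(rr_sd, "rr_sd", min = 0)
  check_number(lv_mean, "lv_mean", min = .Machine$double.eps)
  check_number(lv_sd, "lv_sd", min = 0)
  check_number(ldf_fraction, "ldf_fraction", min = 0, max = 1)
  check_number(pdr_link_noise_sd, "pdr_link_noise_sd", min = 0)
  check_number(survival_log_hazard_per_erlf, "survival_log_hazard_per_erlf")
  check_number(baseline_hazard_per_day, "baseline_hazard_per_day", min = 0)
  check_number(censor_rate, "censor_rate", min = 0)
  check_number(admin_censor_days, "admin_censor_days", min = 1)
  check_number(lab_noise_sd, "lab_noise_sd", min = 0)
  if (!is.data.frame(resection_fractions) ||
      !all(c("type", "fraction", "weight") %in% names(resection_fractions))) {
    abort("`resection_fractions` must have columns type, fraction, weight.")
  }
  check_number(resection_fractions$fraction, "resection_fractions$fraction",
               min = 0, allow_vector = TRUE)
  if (any(resection_fractions$fraction >= 1)) {
    abort("`resection_fractions$fraction` must be < 1 (cannot resect the whole liver).")
  }
  check_number(resection_fractions$weight, "resection_fractions$weight",
               min = 0, allow_vector = TRUE)
  if (!is.null(seed)) check_number(seed, "seed")
  structure(
    list(n = as.integer(n),
         t1_plain_mean = t1_plain_mean, t1_plain_sd = t1_plain_sd,
         rr_mean_nlf = rr_mean_nlf, rr_mean_ldf = rr_mean_ldf, rr_sd = rr_sd,
         lv_mean = lv_mean, lv_sd = lv_sd,
         ldf_fraction = ldf_fraction,
         resection_fractions = tibble::as_tibble(resection_fractions),
         pdr_link_noise_sd = pdr_link_noise_sd,
         survival_log_hazard_per_erlf = survival_log_hazard_per_erlf,
         baseline_hazard_per_day = baseline_hazard_per_day,
         censor_rate = censor_rate,
         admin_censor_days = admin_censor_days,
         lab_noise_sd = lab_noise_sd,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "generator_params"
  )
}
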