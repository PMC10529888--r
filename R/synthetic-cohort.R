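#' Generate a synthetic hepatectomy cohort
#'
#' Draws a cohort with the latent structure the downstream analysis
#' assumes. The generative pipeline, per patient:
#' 1. latent dysfunction status ~ Bernoulli(`ldf_fraction`);
#' 2. T1 reduction rate from the status-specific normal;
#' 3. plain T1 normal, hepatobiliary T1 set to `t1_plain * (1 - rr/100)`
#'    so the T1 pair reproduces the latent rate exactly;
#' 4. liver volume lognormal, moment-matched to `lv_mean`/`lv_sd`;
#' 5. preoperative ICG-PDR = eLF(rr, LV) + Gaussian noise; R15 =
#'    `100 exp(-0.15 PDR)` + noise (clamped to `[0, 100]`);
#' 6. a surgery type drawn from `resection_fractions` fixes the resected
#'    volume as a fraction of LV;
#' 7. postoperative PDR = erLF(rr, remnant volume) + noise, floored at
#'    0.1 %/min;
#' 8. bilirubin/INR on postoperative days 3-7, elevated in proportion to
#'    the postoperative functional deficit when PDR < 10;
#' 9. survival time exponential with log-hazard linear in erLF, with
#'    independent exponential censoring and administrative truncation.
#'
#' With all noise SDs at zero the postoperative PDR equals the erLF score
#' exactly, which makes end-to-end classification exact by construction.
#'
#' @param params A [generator_params()]; generation is deterministic
#'   given `params$seed`.
#' @return A tibble with one row per patient (imaging, volumetric, ICG,
#'   laboratory and survival fields, plus the latent columns
#'   `ldf_latent`, `rr_latent` and `erlf_latent` for calibration checks).
#'   The params used are attached as attribute `provenance`.
#' @examples
#' cohort <- generate_cohort(generator_params(n = 10, seed = 1))
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "generator_params")) {
    abort("`params` must be created by generator_params().")
  }
  cohort <- with_optional_seed(params$seed, generate_cohort_impl(params))
  attr(cohort, "provenance") <- params
  cohort
}

generate_cohort_impl <- function(params) {
  n <- params$n
  coeffs <- model_coefficients()

  ldf <- rbinom(n, 1, params$ldf_fraction) == 1
  rr <- rnorm(n,
              mean = ifelse(ldf, params$rr_mean_ldf, params$rr_mean_nlf),
              sd = params$rr_sd)
  rr <- pmin(rr, 99)  # keep the hepatobiliary T1 positive
  t1_plain <- pmax(rnorm(n, params$t1_plain_mean, params$t1_plain_sd), 1)
  t1_hbp <- t1_plain * (1 - rr / 100)

  # lognormal moment match: mean m, sd s -> sdlog^2 = log(1 + s^2/m^2)
  sdlog <- sqrt(log(1 + (params$lv_sd / params$lv_mean)^2))
  meanlog <- log(params$lv_mean) - sdlog^2 / 2
  lv <- exp(rnorm(n, meanlog, sdlog))

  elf <- estimated_function(rr, lv, coeffs)
  pdr_pre <- pmax(elf + rnorm(n, 0, params$pdr_link_noise_sd), 0.1)
  r15_pre <- pmin(pmax(100 * exp(-0.15 * pdr_pre) +
                         rnorm(n, 0, params$pdr_link_noise_sd), 0), 100)

  idx <- sample.int(nrow(params$resection_fractions), n, replace = TRUE,
                    prob = params$resection_fractions$weight)
  surgery_type <- params$resection_fractions$type[idx]
  resected <- lv * params$resection_fractions$fraction[idx]
  rlv <- lv - resected

  erlf <- estimated_function(rr, rlv, coeffs)
  pdr_post <- pmax(erlf + rnorm(n, 0, params$pdr_link_noise_sd), 0.1)
  r15_post <- pmin(pmax(100 * exp(-0.15 * pdr_post) +
                          rnorm(n, 0, params$pdr_link_noise_sd), 0), 100)

  labs <- generate_labs(pdr_post, params$lab_noise_sd)

  rate <- params$baseline_hazard_per_day *
    exp(params$survival_log_hazard_per_erlf * erlf)
  death <- rexp(n, rate)
  censor <- if (params$censor_rate > 0) rexp(n, params$censor_rate) else Inf
  censor <- pmin(censor, params$admin_censor_days)
  time_days <- pmin(death, censor)
  event <- death <= censor

  dplyr::bind_cols(
    tibble::tibble(
      id = sprintf("P%04d", seq_len(n)),
      ldf_latent = ldf, rr_latent = rr,
      t1_plain = t1_plain, t1_hbp = t1_hbp,
      lv_ml = lv, surgery_type = surgery_type,
      resected_ml = resected, rlv_ml = rlv,
      erlf_latent = erlf,
      pdr_pre = pdr_pre, r15_pre = r15_pre,
      pdr_post = pdr_post, r15_post = r15_post
    ),
    labs,
    tibble::tibble(time_days = time_days, event = event)
  )
}

# Postoperative lab course: stable near baseline unless the measured
# postoperative clearance indicates dysfunction (PDR < 10 %/min), in which
# case bilirubin and INR rise with the functional deficit. Multiplicative
# lognormal noise keeps the labs positive.
generate_labs <- function(pdr_post, lab_noise_sd) {
  n <- length(pdr_post)
  dys <- pdr_post < 10
  deficit <- pmax(10 - pdr_post, 0)
  noise <- function(scale = 1) exp(rnorm(n, 0, lab_noise_sd * scale))

  bili_base <- ifelse(dys, 1.5 + 0.6 * deficit, 0.7)
  inr_base <- ifelse(dys, 1.25 + 0.08 * deficit, 1.05)

  out <- tibble::tibble(
    bili_preop = 0.6 * noise(),
    inr_preop = 1.0 * noise(0.3)
  )
  for (pod in 3:7) {
    out[[paste0("bili_pod", pod)]] <- bili_base * noise()
    out[[paste0("inr_pod", pod)]] <- inr_base * noise(0.3)
  }
  out
}

#' Simulate an ICG concentration curve
#'
#' Monoexponential dye clearance `C(t) = c0 * exp(-(pdr/100) t)` with
#' optional additive Gaussian measurement noise, truncated below at a
#' small positive floor so log-transformation stays defined.
#'
#' @param pdr Plasma disappearance rate, %/min (>= 0).
#' @param c0 Initial concentration, mg/L (> 0).
#' @param times Sampling times in minutes, strictly increasing, >= 0.
#' @param noise_sd Gaussian noise SD, mg/L.
#' @param seed Optional integer seed.
#' @return An [icg_curve()].
#' @examples
#' generate_icg_curve(pdr = 20.2, c0 = 5, times = seq(0, 15, 1))
#' @export
generate_icg_curve <- function(pdr, c0 = 5, times = seq(0, 15, 1),
                               noise_sd = 0, seed = NULL) {
  check_number(pdr, "pdr", min = 0)
  check_number(c0, "c0", min = .Machine$double.eps)
  if (length(times) == 0) abort("`times` must be non-empty.")
  check_number(times, "times", min = 0, allow_vector = TRUE)
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  check_number(noise_sd, "noise_sd", min = 0)
  conc <- with_optional_seed(seed, {
    c0 * exp(-(pdr / 100) * times) + rnorm(length(times), 0, noise_sd)
  })
  icg_curve(times, pmax(conc, 1e-9))
}

#' Generate a phantom segmentation mask
#'
#' Builds a labelled ellipsoidal "liver" on a voxel grid for volumetry
#' testing: functional liver voxels hit the requested volume to within
#' one voxel, a resection plane (orthogonal to the first axis) splits the
#' organ into remnant and resected labels with the resected volume again
#' voxel-exact, and small lesion and vessel structures are embedded near
#' the organ centre (they carry their own labels and never count toward
#' functional liver volume).
#'
#' @param shape Integer vector of 3 grid dimensions.
#' @param spacing Voxel spacing in mm per axis (3 positive values).
#' @param target_liver_ml Target functional liver volume, mL.
#' @param target_resect_ml Target resected volume, mL (0 for none).
#' @param lesion_ml,vessel_ml Embedded structure volumes, mL.
#' @param seed Optional seed (jitters the lesion position).
#' @return A [liver_mask()].
#' @examples
#' m <- generate_phantom_mask(c(32, 32, 32), spacing = c(4, 4, 4),
#'                            target_liver_ml = 800, target_resect_ml = 250)
#' volume_set(m)
#' @export
generate_phantom_mask <- function(shape, spacing, target_liver_ml,
                                  target_resect_ml, lesion_ml = 2,
                                  vessel_ml = 1, seed = NULL) {
  check_number(shape, "shape", min = 1, allow_vector = TRUE)
  if (length(shape) != 3) abort("`shape` must have 3 dimensions.")
  shape <- as.integer(shape)
  check_number(spacing, "spacing", min = .Machine$double.eps, allow_vector = TRUE)
  if (length(spacing) != 3) abort("`spacing` must have 3 values.")
  check_number(target_liver_ml, "target_liver_ml", min = 0)
  check_number(target_resect_ml, "target_resect_ml", min = 0,
               max = target_liver_ml)
  check_number(lesion_ml, "lesion_ml", min = 0)
  check_number(vessel_ml, "vessel_ml", min = 0)

  vox_mm3 <- prod(spacing)
  n_liver <- round(target_liver_ml * 1000 / vox_mm3)
  n_resect <- round(target_resect_ml * 1000 / vox_mm3)
  n_lesion <- round(lesion_ml * 1000 / vox_mm3)
  n_vessel <- round(vessel_ml * 1000 / vox_mm3)
  n_total <- n_liver + n_lesion + n_vessel

  # physical coordinates of voxel centres, organ = ellipsoid at grid centre
  ax <- lapply(1:3, function(a) (seq_len(shape[a]) - (shape[a] + 1) / 2) * spacing[a])
  semi <- shape * spacing * 0.475
  r2 <- outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, `+`),
              (ax[[3]] / semi[3])^2, `+`)
  if (sum(r2 <= 1) < n_total) {
    abort(sprintf(
      "Targets exceed grid capacity: need %d voxels, ellipsoid holds %d.",
      n_total, sum(r2 <= 1)))
  }
  inside <- order(r2)[seq_len(n_total)]  # innermost voxels first

  labels <- array(0L, dim = shape)
  coord1 <- ((inside - 1) %% shape[1]) + 1  # first-axis index of each voxel

  organ <- inside
  if (n_lesion > 0 || n_vessel > 0) {
    jitter <- with_optional_seed(seed, runif(3, -0.1, 0.1))
    centre_mm <- semi * jitter
    idx3 <- arrayInd(organ, shape)
    pos <- sweep(idx3, 2, (shape + 1) / 2) * rep(spacing, each = nrow(idx3))
    d_lesion <- colSums((t(pos) - centre_mm)^2)
    lesion_vox <- organ[order(d_lesion)[seq_len(n_lesion)]]
    # vessel: thin column along the third axis through the organ centre
    d_vessel <- pos[, 1]^2 + pos[, 2]^2
    d_vessel[organ %in% lesion_vox] <- Inf
    vessel_vox <- organ[order(d_vessel)[seq_len(n_vessel)]]
    labels[lesion_vox] <- 3L
    labels[vessel_vox] <- 4L
    organ <- setdiff(organ, c(lesion_vox, vessel_vox))
    coord1 <- ((organ - 1) %% shape[1]) + 1
  }

  # resection plane: peel off exactly n_resect voxels from the high end of
  # the first axis (ties broken by linear index, deterministic)
  liver_order <- order(coord1, organ)
  organ <- organ[liver_order]
  if (n_resect > 0) {
    resected_vox <- organ[seq(length(organ) - n_resect + 1, length(organ))]
    remnant_vox <- organ[seq_len(length(organ) - n_resect)]
    labels[resected_vox] <- 2L
  } else {
    remnant_vox <- organ
  }
  labels[remnant_vox] <- 1L

  liver_mask(labels, spacing = spacing)
}
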