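test_that("cohort generation is deterministic given the seed", {
  p <- generator_params(n = 40, seed = 123)
  expect_identical(generate_cohort(p), generate_cohort(p))

  p2 <- generator_params(n = 40, seed = 124)
  expect_false(identical(generate_cohort(p)$lv_ml, generate_cohort(p2)$lv_ml))
})

test_that("with all noise off the postoperative PDR equals the latent erLF", {
  p <- generator_params(n = 80, seed = 7, pdr_link_noise_sd = 0, lab_noise_sd = 0)
  co <- generate_cohort(p)
  expect_identical(co$pdr_post, pmax(co$erlf_latent, 0.1))
  expect_true(all(co$pdr_post == co$erlf_latent))  # erLF far above the floor
  # and the T1 pair encodes the latent reduction rate to numerical precision
  rr <- reduction_rate(co$t1_plain, co$t1_hbp)
  expect_lt(max(abs(rr - co$rr_latent) / abs(co$rr_latent)), 1e-9)
})

test_that("large-cohort marginals match the emulated study characteristics", {
  co <- generate_cohort(generator_params(n = 5000, seed = 11))
  se_lv <- sd(co$lv_ml) / sqrt(nrow(co))
  expect_lt(abs(mean(co$lv_ml) - 1609), 3 * se_lv)
  se_t1 <- sd(co$t1_plain) / sqrt(nrow(co))
  expect_lt(abs(mean(co$t1_plain) - 751.9), 3 * se_t1)
})

test_that("latent dysfunction depresses the reduction rate detectably", {
  co <- generate_cohort(generator_params(n = 5000, seed = 19))
  ldf_rr <- co$rr_latent[co$ldf_latent]
  nlf_rr <- co$rr_latent[!co$ldf_latent]
  expect_lt(mean(ldf_rr), mean(nlf_rr))
  expect_lt(mann_whitney(ldf_rr, nlf_rr)$p_value, 0.01)
})

test_that("preoperative PDR tracks the function score at default noise", {
  sc <- small_cohort(n = 5000, seed = 23)
  expect_gt(cor(sc$pdr_pre, sc$elf), 0.8)
})

test_that("Cox refits recover the simulated survival link", {
  true_beta <- log(0.87)
  covered <- vapply(1:100, function(s) {
    p <- generator_params(n = 5000, seed = 1000 + s, pdr_link_noise_sd = 0,
                          lab_noise_sd = 0)
    sc <- score_cohort(generate_cohort(p))
    fit <- cox_univariable(sc, "erlf")
    fit$beta - 1.96 * fit$se <= true_beta && true_beta <= fit$beta + 1.96 * fit$se
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("invalid generator parameters are rejected naming the field", {
  expect_error(generator_params(n = 0), "n")
  expect_error(generator_params(n = 10, t1_plain_sd = -1), "t1_plain_sd")
  expect_error(generator_params(n = 10, ldf_fraction = 1.2), "ldf_fraction")
  expect_error(generator_params(n = 10, lv_mean = NaN), "lv_mean")
  bad_rf <- data.frame(type = "total", fraction = 1, weight = 1)
  expect_error(generator_params(n = 10, resection_fractions = bad_rf), "fraction")
})

test_that("simulated ICG curves follow the monoexponential closed form", {
  flat <- generate_icg_curve(pdr = 0, c0 = 4, times = 0:5, noise_sd = 0)
  expect_equal(flat$conc_mg_per_l, rep(4, 6))

  cur <- generate_icg_curve(pdr = 20.2, c0 = 5, times = c(0, 5, 15), noise_sd = 0)
  expect_equal(cur$conc_mg_per_l[3], 5 * exp(-3.03), tolerance = 1e-12)

  expect_error(generate_icg_curve(pdr = 20, c0 = 5, times = numeric(0)), "non-empty")
  expect_error(generate_icg_curve(pdr = -1, c0 = 5, times = 0:3), "pdr")
})

test_that("noiseless curve generation and fitting are inverse operations", {
  for (pdr in c(3.7, 10, 17, 20.2, 31.5)) {
    fit <- fit_monoexponential(generate_icg_curve(pdr, c0 = 5, times = 0:10))
    expect_equal(fit$pdr, pdr, tolerance = 1e-9)
    expect_equal(fit$c0, 5, tolerance = 1e-9)
  }
})

test_that("phantom masks hit their target volumes to within one voxel", {
  vox_ml <- 1e-3  # 1 mm^3 voxels
  m <- generate_phantom_mask(c(150, 150, 150), c(1, 1, 1),
                             target_liver_ml = 1000, target_resect_ml = 0)
  expect_equal(mask_volume(m, c("remnant", "resected")), 1000, tolerance = vox_ml)
  expect_false(any(m == attr(m, "label_map")[["resected"]]))

  m2 <- generate_phantom_mask(c(96, 96, 96), c(2, 2, 2),
                              target_liver_ml = 1609, target_resect_ml = 508)
  vs <- volume_set(m2)
  vox_ml2 <- prod(c(2, 2, 2)) / 1000
  expect_lte(abs(vs$lv_ml - 1609), vox_ml2)
  expect_lte(abs(vs$resected_ml - 508), vox_ml2)

  expect_error(
    generate_phantom_mask(c(20, 20, 20), c(1, 1, 1),
                          target_liver_ml = 1000, target_resect_ml = 0),
    "capacity")
})
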