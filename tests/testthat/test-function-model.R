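test_that("reduction rate follows the T1 shortening formula", {
  expect_identical(reduction_rate(800, 200), 75)
  expect_identical(reduction_rate(640, 640), 0)
  # column means of the emulated cohort (mean-of-ratios differs from
  # ratio-of-means, so this is close to but distinct from the cohort RR)
  expect_equal(reduction_rate(751.9, 310.2), 58.744514, tolerance = 1e-6)
  expect_error(reduction_rate(0, 200), "positive")
  expect_error(reduction_rate(-5, 200), "positive")
  expect_warning(rr <- reduction_rate(500, 600), "exceed")
  expect_lt(rr, 0)
})

test_that("function estimate matches high-precision evaluation", {
  expect_identical(estimated_function(0, 0), 0.84)
  # frozen from direct evaluation of 0.84*exp(0.038*58.4)*exp(0.00045*v)
  expect_equal(estimated_function(58.4, 1609), 15.9410352, tolerance = 1e-7)
  expect_equal(estimated_function(58.4, 1176), 13.1188038, tolerance = 1e-7)
  expect_lt(estimated_function(58.4, 1176), estimated_function(58.4, 1609))
  expect_error(estimated_function(50, -10), ">= 0")
})

test_that("function estimate is strictly increasing in rate and volume", {
  rr <- seq(20, 90, by = 5)
  expect_true(all(diff(estimated_function(rr, rep(1500, length(rr)))) > 0))
  vol <- seq(0, 2500, by = 100)
  expect_true(all(diff(estimated_function(rep(55, length(vol)), vol)) > 0))
})

test_that("remnant estimate never exceeds the whole-liver estimate", {
  sc <- small_cohort(n = 300, seed = 31)
  expect_true(all(sc$rlv_ml <= sc$lv_ml))
  expect_true(all(sc$erlf <= sc$elf))
  expect_true(all(sc$erlf[sc$resected_ml > 0] < sc$elf[sc$resected_ml > 0]))
})

test_that("cohort-mean function estimate shows the Jensen direction", {
  for (seed in c(5, 17, 29)) {
    sc <- small_cohort(n = 250, seed = seed)
    expect_gt(mean(sc$elf), estimated_function(mean(sc$rr), mean(sc$lv_ml)))
    expect_gt(mean(sc$erlf), estimated_function(mean(sc$rr), mean(sc$rlv_ml)))
  }
})

test_that("erLF classes replicate the postoperative ICG partition", {
  expect_equal(as.character(classify_erlf(18.6)), "PNLF")
  expect_equal(as.character(classify_erlf(9.5)), "PLDF")
  expect_equal(as.character(classify_erlf(10.0)), "at_risk")
  grid <- seq(0, 30, by = 0.1)
  expect_identical(classify_erlf(grid), classify_postop(grid))
})

test_that("bilirubin conversion uses the molar mass", {
  expect_equal(round(convert_bilirubin(50), 2), 2.92)
  expect_identical(convert_bilirubin(0), 0)
  expect_equal(round(convert_bilirubin(100), 2), 5.85)
  expect_error(convert_bilirubin(-1), ">= 0")
})

baseline_series <- function(value) data.frame(pod = 3:7, value = value)

test_that("outcome flags implement dysfunction, 50/50 and peak-bilirubin rules", {
  # 50/50 met on POD 5
  out <- clinical_outcome(
    preop_bili = 0.6,
    bili_series = data.frame(pod = 3:7, value = c(1.0, 2.0, 3.0, 2.0, 1.5)),
    preop_inr = 1.0,
    inr_series = data.frame(pod = 3:7, value = c(1.1, 1.4, 1.8, 1.5, 1.2)))
  expect_true(out$severe_failure)
  expect_true(out$acute_dysfunction)

  # peak bilirubin above 7 mg/dL alone
  out2 <- clinical_outcome(0.6, data.frame(pod = 4, value = 7.5),
                           1.0, data.frame(pod = 4, value = 1.0))
  expect_true(out2$severe_failure)

  # everything at baseline
  out3 <- clinical_outcome(0.6, baseline_series(0.6), 1.0, baseline_series(1.0))
  expect_false(out3$acute_dysfunction)
  expect_false(out3$severe_failure)

  # dysfunction needs both the cut-off and a rise above baseline
  out4 <- clinical_outcome(2.5, baseline_series(2.4), 1.0, baseline_series(1.1))
  expect_false(out4$acute_dysfunction)
  out5 <- clinical_outcome(0.6, baseline_series(1.2), 1.0, baseline_series(1.0))
  expect_true(out5$acute_dysfunction)
  expect_false(out5$severe_failure)

  # 50/50 needs bilirubin and INR elevated on the same day
  out6 <- clinical_outcome(
    0.6, data.frame(pod = c(3, 5), value = c(3.5, 0.8)),
    1.0, data.frame(pod = c(3, 5), value = c(1.1, 1.9)))
  expect_false(out6$severe_failure)
  expect_true(out6$acute_dysfunction)
})

test_that("outcome evaluation warns when the window is uncovered and rejects bad input", {
  expect_warning(
    clinical_outcome(0.6, data.frame(pod = 10, value = 5),
                     1.0, data.frame(pod = 10, value = 2)),
    "window")
  expect_error(
    clinical_outcome(0.6, data.frame(pod = 95, value = 1), 1.0,
                     baseline_series(1)),
    "pod")
  expect_error(
    clinical_outcome(0.6, data.frame(pod = 4, value = -2), 1.0,
                     baseline_series(1)),
    "positive")
})

test_that("severe failure implies acute dysfunction on generated lab courses", {
  sc <- small_cohort(n = 400, seed = 53)
  report <- run_pipeline(run_config(params = generator_params(n = 150, seed = 53)))
  expect_true(all(!report$cohort$severe_failure | report$cohort$acute_dysfunction))
})

test_that("scoring is idempotent and validates volumes", {
  sc <- small_cohort(n = 30, seed = 3)
  expect_identical(score_cohort(sc), sc)
  bad <- sc
  bad$resected_ml[1] <- bad$lv_ml[1] + 1
  expect_error(score_cohort(bad), "exceeds")
  expect_error(score_cohort(sc[, setdiff(names(sc), "t1_plain")]), "t1_plain")
})
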