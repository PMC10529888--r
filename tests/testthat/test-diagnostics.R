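test_that("confusion counts agree with construction and swap under inversion", {
  ref <- rep(c(TRUE, FALSE), times = c(19, 52))
  pred <- c(rep(c(TRUE, FALSE), times = c(10, 9)),
            rep(c(TRUE, FALSE), times = c(6, 46)))
  cm <- confusion(pred, ref)
  expect_identical(c(cm$tp, cm$fp, cm$tn, cm$fn), c(10L, 6L, 46L, 9L))

  inv <- confusion(!pred, ref)
  expect_identical(c(inv$tp, inv$fn), c(cm$fn, cm$tp))
  expect_identical(c(inv$tn, inv$fp), c(cm$fp, cm$tn))

  perfect <- confusion(ref, ref)
  expect_identical(c(perfect$fp, perfect$fn), c(0L, 0L))
  expect_error(confusion(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("metrics are the defining ratios, NA on empty denominators", {
  m <- diagnostic_metrics(confusion_matrix(10, 12, 40, 9))
  expect_equal(m$accuracy, 50 / 71)
  expect_equal(m$ppv, 10 / 22)
  expect_equal(m$npv, 40 / 49)
  expect_equal(m$sensitivity, 10 / 19)
  expect_equal(m$specificity, 40 / 52)

  m2 <- diagnostic_metrics(confusion_matrix(10, 6, 46, 9))
  expect_equal(m2$accuracy, 56 / 71)
  expect_equal(m2$ppv, 0.625)
  expect_equal(m2$npv, 46 / 55)

  all_right <- diagnostic_metrics(confusion_matrix(5, 0, 7, 0))
  expect_true(all(as.numeric(all_right) == 1))

  undef_ppv <- diagnostic_metrics(confusion_matrix(0, 0, 12, 0))
  expect_true(is.na(undef_ppv$ppv))
  expect_false(identical(undef_ppv$ppv, 0))
})

test_that("metrics are invariant under record permutation", {
  withr::with_seed(42, {
    ref <- runif(60) < 0.3
    pred <- runif(60) < 0.4
    perm <- sample(60)
    expect_identical(diagnostic_metrics(confusion(pred, ref)),
                     diagnostic_metrics(confusion(pred[perm], ref[perm])))
  })
})

test_that("reconstruction from rounded anchors finds the unique matrix", {
  cm <- reconstruct_confusion(19, 52, c(sensitivity = 0.53, specificity = 0.77))
  expect_true(attr(cm, "unique"))
  expect_identical(c(cm$tp, cm$tn), c(10L, 40L))

  cm2 <- reconstruct_confusion(19, 52, c(sensitivity = 0.53, accuracy = 0.79))
  expect_true(attr(cm2, "unique"))
  expect_identical(c(cm2$tp, cm2$tn), c(10L, 46L))

  expect_error(reconstruct_confusion(19, 52, c(sensitivity = 1.01)),
               "cannot be attained")
  expect_error(reconstruct_confusion(19, 52, c(sensitivity = 0.53,
                                               specificity = 0.53,
                                               accuracy = 0.99)),
               "No integer matrix")
})

test_that("reconstruction inverts metric rounding on random matrices", {
  withr::with_seed(7, {
    for (i in 1:25) {
      n_pos <- sample(5:100, 1)
      n_neg <- sample(5:100, 1)
      tp <- sample(0:n_pos, 1)
      tn <- sample(0:n_neg, 1)
      cm <- confusion_matrix(tp, n_neg - tn, tn, n_pos - tp)
      met <- diagnostic_metrics(cm)
      anchors <- c(sensitivity = round(met$sensitivity + 1e-12, 2),
                   specificity = round(met$specificity + 1e-12, 2))
      rec <- suppressWarnings(reconstruct_confusion(n_pos, n_neg, anchors))
      back <- diagnostic_metrics(rec)
      expect_equal(round(back$sensitivity + 1e-12, 2), anchors[["sensitivity"]])
      expect_equal(round(back$specificity + 1e-12, 2), anchors[["specificity"]])
    }
  })
})

test_that("printed-value comparison surfaces disagreements instead of hiding them", {
  cm <- confusion_matrix(10, 6, 46, 9)
  rep <- printed_metric_report(cm, c(ppv = 0.63, specificity = 0.89))
  expect_true(rep$agrees[rep$metric == "ppv"])
  expect_false(rep$agrees[rep$metric == "specificity"])
  expect_equal(rep$rounded[rep$metric == "specificity"], 0.88)
})

test_that("AUC handles separation, pure ties, and a worked mixed example", {
  expect_identical(roc_auc(c(1, 2, 10, 11), c(TRUE, TRUE, FALSE, FALSE),
                           "lower_is_positive"), 1)
  expect_identical(roc_auc(rep(3, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                           "lower_is_positive"), 0.5)

  scores <- c(2, 5, 5, 7, 9, 12)
  ref <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(scores, ref, "lower_is_positive"),
               auc_pairwise_oracle(scores, ref, lower_is_positive = TRUE))

  expect_equal(roc_auc(scores, ref, "higher_is_positive"),
               1 - roc_auc(scores, ref, "lower_is_positive"))
  expect_error(roc_auc(1:4, rep(TRUE, 4), "lower_is_positive"), "Both classes")
})

test_that("AUC equals the pairwise concordance oracle on random instances", {
  withr::with_seed(99, {
    for (i in 1:100) {
      n <- sample(4:50, 1)
      ref <- c(TRUE, FALSE, runif(n - 2) < 0.5)  # both classes guaranteed
      scores <- sample(1:10, n, replace = TRUE)  # heavy ties
      expect_equal(roc_auc(scores, ref, "lower_is_positive"),
                   auc_pairwise_oracle(scores, ref))
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(5, {
    scores <- rnorm(40)
    ref <- runif(40) < 0.4
    ours <- roc_auc(scores, ref, "higher_is_positive")
    theirs <- as.numeric(pROC::auc(pROC::roc(
      response = ref, predictor = scores, direction = "<", quiet = TRUE)))
    expect_equal(ours, theirs)
  })
})

test_that("Mann-Whitney exact enumeration matches hand-counted cases", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_identical(res$u_statistic, 0)
  expect_equal(res$p_value, 1 / 3)
  expect_identical(res$method, "exact")

  tie <- mann_whitney(2.5, 2.5)
  expect_identical(tie$u_statistic, 0.5)

  same <- mann_whitney(c(1, 4, 4), c(4, 1, 4))
  expect_identical(same$p_value, 1)
})

test_that("exact and approximate Mann-Whitney branches agree near the switch", {
  withr::with_seed(13, {
    for (i in 1:30) {
      a <- rnorm(6)
      b <- rnorm(6, mean = 0.5)
      exact <- mann_whitney(a, b)$p_value
      approx <- mann_whitney(a, b, exact_limit = 0)$p_value
      expect_lte(abs(exact - approx), 0.05)
    }
  })
})

test_that("approximate branch tracks the reference rank-sum test", {
  withr::with_seed(21, {
    a <- rnorm(20)
    b <- rnorm(25, mean = 0.8)
    ours <- mann_whitney(a, b)
    ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(ours$u_statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  })
})
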