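confusion_to_pairs <- function(cm) {
  # expand a 2x2 confusion (ref in rows 0/1, pred in cols 0/1) to vectors
  ref <- pred <- integer(0)
  for (r in 0:1) for (p in 0:1) {
    k <- cm[r + 1, p + 1]
    ref <- c(ref, rep(r, k))
    pred <- c(pred, rep(p, k))
  }
  list(ref = ref, pred = pred)
}

test_that("epoch metrics reproduce hand-computed kappa values", {
  x <- confusion_to_pairs(matrix(c(40, 10, 5, 45), 2, byrow = TRUE))
  em <- epoch_metrics(x$pred, x$ref)
  expect_equal(as.numeric(em$kappa), 0.70)   # (0.85 - 0.5) / (1 - 0.5)

  perfect <- epoch_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_equal(as.numeric(perfect$kappa), 1)
  expect_equal(perfect$sleep$f1, 1)
  expect_equal(perfect$wake$f1, 1)

  chance <- confusion_to_pairs(matrix(c(25, 25, 25, 25), 2))
  expect_equal(as.numeric(epoch_metrics(chance$pred, chance$ref)$kappa), 0)

  one_class <- epoch_metrics(c(1, 1, 0), c(1, 1, 1))
  expect_true(is.na(one_class$kappa))
  expect_match(attr(one_class$kappa, "reason"), "single class")
})

test_that("kappa, F1, sensitivity and specificity agree with established implementations", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("caret")
  set.seed(31)
  for (k in 1:100) {
    cm <- matrix(rpois(4, 20) + 1, 2)
    x <- confusion_to_pairs(cm)
    em <- epoch_metrics(x$pred, x$ref)
    expect_equal(as.numeric(em$kappa),
                 e1071::classAgreement(t(cm))$kappa, tolerance = 1e-12)
    ref_f <- factor(x$ref, levels = c(1, 0))
    pred_f <- factor(x$pred, levels = c(1, 0))
    expect_equal(em$sleep$sensitivity,
                 caret::sensitivity(pred_f, ref_f), tolerance = 1e-12)
    expect_equal(em$sleep$specificity,
                 caret::specificity(pred_f, ref_f), tolerance = 1e-12)
    cmat <- caret::confusionMatrix(pred_f, ref_f, mode = "prec_recall")
    expect_equal(em$sleep$f1, unname(cmat$byClass["F1"]),
                 tolerance = 1e-12)
  }
})

test_that("TST, AHI and REI estimators follow their definitions", {
  expect_equal(estimate_tst(rep(1, 840)), 7)
  expect_equal(estimate_ahi(35, 7), 5)
  expect_equal(estimate_rei(35, 8), 4.375)
  # AHI >= REI whenever TST <= TIB
  set.seed(32)
  for (k in 1:20) {
    n <- rpois(1, 30)
    tib <- runif(1, 5, 9)
    tst <- runif(1, 0.5, 1) * tib
    expect_gte(estimate_ahi(n, tst), estimate_rei(n, tib))
  }
  und <- estimate_ahi(3, 0)
  expect_true(is.na(und))
  expect_match(attr(und, "reason"), "TST = 0")
  expect_equal(estimate_ahi(0, 0), 0)
})

test_that("severity classes use half-open boundaries", {
  expect_equal(as.character(severity_class(c(0, 4.9, 5, 14.9, 15, 29.9,
                                             30, 100))),
               c("normal", "normal", "mild", "mild", "moderate",
                 "moderate", "severe", "severe"))
  expect_error(severity_class(-1), "non-negative")
})

test_that("near-boundary double-labeling returns flanking classes in zones", {
  expect_equal(nbl_classes(10), "mild")
  expect_equal(nbl_classes(15 + 0.5 * 1.5), c("mild", "moderate"))
  expect_equal(nbl_classes(4.6), c("normal", "mild"))
  expect_equal(nbl_classes(33), c("moderate", "severe"))
  expect_equal(nbl_classes(40), "severe")
  expect_error(nbl_classes(-2), "non-negative")
})

test_that("NBL accuracy dominates plain accuracy", {
  ref <- c(3, 10, 14, 45)
  est_zone <- c(3, 10, 16, 45)      # one class miss just inside the 15-zone
  plain <- severity_confusion(ref, est_zone, nbl = FALSE)
  nbl <- severity_confusion(ref, est_zone, nbl = TRUE)
  expect_equal(plain$accuracy, 0.75)
  expect_equal(nbl$accuracy, 1)
  expect_equal(sum(diag(nbl$confusion)), 4)

  same <- severity_confusion(ref, ref, nbl = FALSE)
  expect_equal(same$accuracy, 1)
  expect_equal(same$kappa, 1)

  set.seed(33)
  for (k in 1:25) {
    r <- runif(8, 0, 60)
    e <- pmax(0, r + rnorm(8, 0, 8))
    expect_gte(severity_confusion(r, e, nbl = TRUE)$accuracy,
               severity_confusion(r, e, nbl = FALSE)$accuracy)
  }
})

test_that("agreement statistics match definition-level oracles", {
  set.seed(34)
  ref <- runif(20, 0, 60)
  est <- ref + rnorm(20, 1, 5)
  ba <- bland_altman(ref, est)
  ob <- oracle_bland_altman(ref, est)
  expect_lt(abs(ba$bias - ob$bias), 1e-10)
  expect_lt(abs(ba$loa_low - ob$loa_low), 1e-10)
  expect_lt(abs(ba$loa_high - ob$loa_high), 1e-10)
  expect_lt(abs(spearman_r(ref, est) - oracle_spearman(ref, est)), 1e-10)
  expect_lt(abs(mae(ref, est) - sum(abs(est - ref)) / 20), 1e-10)

  expect_equal(bland_altman(ref, ref),
               list(bias = 0, loa_low = 0, loa_high = 0, sd = 0))
  shift <- bland_altman(ref, ref + 1)
  expect_equal(shift$bias, 1)
  expect_equal(c(shift$loa_low, shift$loa_high), c(1, 1))
  expect_equal(as.numeric(spearman_r(ref, ref)), 1)
  expect_equal(mae(ref, ref + 1), 1)
  expect_true(is.na(spearman_r(rep(1, 5), 1:5)))
})

test_that("the sleep-efficiency sweep subsets monotonically", {
  set.seed(35)
  rep_df <- data.frame(se_ref = runif(24, 0.4, 1),
                       ahi_ref = runif(24, 0, 60))
  rep_df$ahi_est <- pmax(0, rep_df$ahi_ref + rnorm(24, 0, 3))
  rep_df$rei_est <- rep_df$ahi_ref * rep_df$se_ref   # TIB-diluted index
  sw <- efficiency_sweep(rep_df, cutoffs = c(0.5, 0.7, 0.9, 1))
  expect_equal(sw$n[sw$cutoff == 1], 24)
  expect_true(all(diff(sw$n) >= 0))
  # REI denominator inflation hurts most at low sleep efficiency
  low <- sw[sw$cutoff == 0.5, ]
  if (!is.na(low$mae_rei)) expect_gt(low$mae_rei, low$mae_ahi)
  # sparse subsets are reported missing
  sw2 <- efficiency_sweep(rep_df[1:4, ], cutoffs = c(0.05, 1))
  expect_true(is.na(sw2$r_ahi[1]))
})
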