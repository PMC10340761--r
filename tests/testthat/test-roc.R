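test_that("perfectly separated groups give AUC 1 and a perfect cutoff", {
  roc <- suppressWarnings(
    marker_roc(c(1, 2, 8, 9), factor(c("met", "met", "nonmet", "nonmet"),
                                     c("nonmet", "met")), "low_positive"))
  expect_equal(roc$auc, 1)
  roc2 <- suppressWarnings(
    marker_roc(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0), "low_positive"))
  expect_equal(roc2$cutoff, 3)
  expect_equal(roc2$cutoff_rule, "<= 3")
  expect_equal(roc2$sensitivity, 100)
  expect_equal(roc2$specificity, 100)
  expect_equal(roc2$youden_j, 1)
  expect_error(marker_roc(1:4, c(1, 1, 1, 1), "low_positive"), "both outcome classes")
})

test_that("ROC points are monotone and AUC is transform- and flip-consistent", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    v <- rnorm(n)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    roc <- marker_roc(v, y, "high_positive")
    expect_true(all(diff(roc$points$fpr) >= 0))
    expect_true(all(diff(roc$points$tpr) >= 0))
    # strictly increasing transforms leave the curve alone
    roc_t <- marker_roc(exp(v), y, "high_positive")
    expect_equal(roc$auc, roc_t$auc, tolerance = 1e-12)
    # flipping the direction mirrors the AUC on tie-free data
    roc_f <- marker_roc(v, y, "low_positive")
    expect_equal(roc$auc, 1 - roc_f$auc, tolerance = 1e-12)
  }
})

test_that("reported sensitivity and specificity match a confusion recount", {
  cohort <- simulate_cohort(tiny_config(seed = 42))
  met <- cohort$outcome == "met"
  for (m in c("CA9", "MIR125B1")) {
    dir <- if (m == "CA9") "low_positive" else "high_positive"
    roc <- marker_roc(cohort[[m]], cohort$outcome, dir, marker = m)
    v <- cohort[[m]]
    call <- if (dir == "low_positive") v <= roc$cutoff else v > roc$cutoff
    expect_equal(roc$sensitivity, 100 * sum(call & met) / sum(met))
    expect_equal(roc$specificity, 100 * sum(!call & !met) / sum(!met))
    expect_equal(roc$youden_j,
                 roc$sensitivity / 100 + roc$specificity / 100 - 1)
  }
})

test_that("Youden ties break toward the higher specificity", {
  # two thresholds reach J = 0.5: "<= 1" (sens 50, spec 100) and "<= 4"
  # (sens 100, spec 50); the more specific rule must win
  v <- c(1, 4, 4, 10)
  y <- c(1, 1, 0, 0)
  roc <- marker_roc(v, y, "low_positive")
  expect_equal(roc$cutoff, 1)
  expect_equal(roc$specificity, 100)
})

test_that("DeLong interval brackets the estimate; null data give p near 1", {
  # antisymmetric toy data: AUC exactly 0.5
  v <- c(1, 2, 3, 4, 1, 2, 3, 4)
  y <- c(1, 1, 0, 0, 0, 0, 1, 1)
  roc <- marker_roc(v, y, "high_positive")
  expect_equal(roc$auc, 0.5)
  expect_equal(roc$p_vs_half, 1)
  cohort <- simulate_cohort(tiny_config(seed = 13))
  roc2 <- marker_roc(cohort$CA9, cohort$outcome, "low_positive")
  expect_true(roc2$auc_ci_low <= roc2$auc && roc2$auc <= roc2$auc_ci_high)
  expect_warning(marker_roc(c(1, 2, 8, 9), c(1, 1, 0, 0), "low_positive"),
                 "degenerate")
})

test_that("AUC and DeLong variance agree with an independent implementation", {
  cohort <- simulate_cohort(tiny_config(seed = 77))
  for (m in c("CA9", "MIR125B1")) {
    dir <- if (m == "CA9") "low_positive" else "high_positive"
    roc <- marker_roc(cohort[[m]], cohort$outcome, dir)
    pr <- pROC::roc(cohort$outcome, cohort[[m]], quiet = TRUE,
                    direction = if (dir == "low_positive") ">" else "<",
                    levels = c("nonmet", "met"))
    expect_equal(roc$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(roc$auc_ci_low, ci[1], tolerance = 1e-9)
    expect_equal(roc$auc_ci_high, ci[3], tolerance = 1e-9)
  }
})

test_that("labels independent of the values give AUC near one half", {
  set.seed(99)
  v <- rnorm(1000)
  y <- rbinom(1000, 1, 0.4)
  roc <- marker_roc(v, y, "high_positive")
  expect_lt(abs(roc$auc - 0.5), 0.05)
})

test_that("roc_summary applies modality directions and collects all markers", {
  cohort <- simulate_cohort(tiny_config(seed = 55))
  out <- roc_summary(cohort)
  expect_equal(out$marker, c("CA9", "MIR125B1"))
  expect_match(out$cutoff_rule[out$marker == "CA9"], "^<= ")
  expect_match(out$cutoff_rule[out$marker == "MIR125B1"], "^> ")
  rocs <- attr(out, "rocs")
  expect_equal(rocs$CA9$auc, out$auc[1])
})
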