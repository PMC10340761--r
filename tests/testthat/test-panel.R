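test_that("event rules honour the published cutoffs and boundary conventions", {
  cohort <- data.frame(
    sample_id = c("a", "b", "c"),
    CA9 = c(17.8, 51.3, 60),          # expression: event when <= 51.3 (inclusive)
    MIR125B1 = c(66.34, 55.18, 50),   # methylation: event when > 55.18 (strict)
    stringsAsFactors = FALSE
  )
  panel <- panel_definition("toy", c("CA9", "MIR125B1"),
                            c("low_positive", "high_positive"),
                            c(51.3, 55.18), 1)
  ev <- call_events(cohort, panel)
  expect_equal(unname(ev[, "CA9"]), c(1L, 1L, 0L))       # equality counts
  expect_equal(unname(ev[, "MIR125B1"]), c(1L, 0L, 0L))  # equality does not
  expect_error(call_events(cohort[, 1:2], panel), "MIR125B1")
})

test_that("samples with a missing panel marker are excluded and counted", {
  cohort <- simulate_cohort(tiny_config(seed = 8))
  cohort$CA9[c(2, 5)] <- NA
  panel <- panel_definition("toy", c("CA9", "MIR125B1"),
                            c("low_positive", "high_positive"), c(50, 50), 1)
  ev <- call_events(cohort, panel)
  expect_equal(nrow(ev), 78)
  expect_setequal(attr(ev, "excluded"), cohort$sample_id[c(2, 5)])
})

test_that("count-rule calls fire at k or more events", {
  ev <- rbind(a = c(1, 1, 1, 0), b = c(1, 1, 0, 0), c = c(0, 0, 0, 0))
  out <- classify_count_rule(ev, 3)
  expect_equal(out$call, c(1L, 0L, 0L))
  expect_equal(out$count, c(3L, 2L, 0L))
  # five of nine events is below the six-event rule
  ev9 <- matrix(c(rep(1, 5), rep(0, 4)), 1)
  expect_equal(classify_count_rule(ev9, 6)$call, 0L)
  # k = 1 degenerates to a logical OR
  expect_equal(classify_count_rule(ev, 1)$call, as.integer(rowSums(ev) >= 1))
  expect_error(classify_count_rule(ev, 5), "exceeds")
  expect_error(classify_count_rule(ev * 2, 2), "binary")
})

test_that("panel performance reproduces the reference predictive values", {
  # confusion (tp 27, fp 2, tn 47, fn 4): the reference combined panel
  outcome <- rep(c(1, 0), c(31, 49))
  pred <- c(rep(1, 27), rep(0, 4), rep(1, 2), rep(0, 47))
  perf <- panel_performance(pred, pred * 9, outcome)
  expect_equal(perf$tp, 27); expect_equal(perf$fp, 2)
  expect_equal(perf$tn, 47); expect_equal(perf$fn, 4)
  expect_equal(round(perf$npv, 2), 92.16)
  expect_equal(round(perf$ppv, 2), 93.10)
  expect_equal(round(perf$sensitivity, 2), 87.10)
  expect_equal(round(perf$specificity, 2), 95.92)
  # Clopper-Pearson intervals bracket the point estimates
  expect_true(perf$npv_ci[1] < perf$npv && perf$npv < perf$npv_ci[2])
  expect_true(perf$sensitivity_ci[1] < perf$sensitivity)
})

test_that("degenerate denominators are reported as undefined, not numbers", {
  outcome <- c(1, 1, 0, 0)
  perf <- panel_performance(c(0, 0, 0, 0), c(0, 0, 0, 0), outcome)
  expect_true(is.na(perf$ppv))
  expect_equal(perf$specificity, 100)
  perfect <- panel_performance(outcome, outcome, outcome)
  expect_equal(c(perfect$sensitivity, perfect$specificity,
                 perfect$ppv, perfect$npv), rep(100, 4))
})

test_that("sensitivity falls and specificity rises as k increases", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(10:40, 1); m <- sample(2:9, 1)
    ev <- matrix(rbinom(n * m, 1, runif(1, 0.2, 0.8)), n, m)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    sens <- spec <- numeric(m)
    for (k in 1:m) {
      cl <- classify_count_rule(ev, k)
      sens[k] <- mean(cl$call[y == 1]); spec[k] <- mean(cl$call[y == 0] == 0)
    }
    expect_true(all(diff(sens) <= 0))
    expect_true(all(diff(spec) >= 0))
  }
})

test_that("the count-score ROC passes through every k-rule operating point", {
  set.seed(62)
  for (i in 1:20) {
    n <- sample(10:30, 1); m <- sample(2:6, 1)
    ev <- matrix(rbinom(n * m, 1, 0.5), n, m)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    cl <- classify_count_rule(ev, 1)
    count <- cl$count
    # the ordinal score exposes each k-of-m rule as the threshold "count >= k"
    for (k in 1:m) {
      ck <- classify_count_rule(ev, k)
      expect_equal(ck$call, as.integer(count >= k))
    }
  }
})

test_that("confusion matrices reconstruct exactly from reported rates", {
  expect_equal(reconstruct_confusion(87.10, 95.92, 31, 49),
               c(tp = 27L, fp = 2L, tn = 47L, fn = 4L))
  expect_equal(reconstruct_confusion(74.19, 79.59, 31, 49),
               c(tp = 23L, fp = 10L, tn = 39L, fn = 8L))
  expect_equal(reconstruct_confusion(100, 100, 10, 10),
               c(tp = 10L, fp = 0L, tn = 10L, fn = 0L))
  expect_error(reconstruct_confusion(87.10, 90.00, 31, 49), "inconsistent")
})

test_that("count_panel fits, predicts and summarises as a model object", {
  cohort <- simulate_cohort(sim_config(seed = 2))
  fit <- count_panel(cohort, cutoffs = "reference", name = "COMBINED9")
  expect_s3_class(fit, "count_panel")
  expect_equal(fit$definition$k_events, 6L)
  expect_equal(names(coef(fit)),
               builtin_panels()$COMBINED9$markers$marker)
  # predicting on the fitting cohort reproduces the stored calls
  expect_equal(predict(fit, cohort), fit$calls)
  perf <- summary(fit)
  expect_s3_class(perf, "panel_performance")
  expect_equal(perf$tp + perf$fn, 31)
  expect_output(print(fit), "COMBINED9")
  expect_output(print(perf), "sensitivity")
  # auto cutoffs come from the per-marker Youden analysis
  fit2 <- count_panel(cohort, cutoffs = "auto", name = "auto9")
  rs <- roc_summary(cohort)
  expect_equal(unname(coef(fit2)),
               rs$cutoff[match(names(coef(fit2)), rs$marker)])
  expect_error(count_panel(cohort, markers = c("CA9", "NOPE")), "NOPE")
})

test_that("builtin panels carry the published membership and thresholds", {
  p <- builtin_panels()
  expect_equal(vapply(p, function(x) x$k_events, integer(1)),
               c(EXPR4 = 3L, METH5 = 4L, COMBINED9 = 6L))
  expect_equal(p$EXPR4$markers$cutoff, c(51.3, 22, 4.2, 2.6))
  expect_equal(p$METH5$markers$direction, rep("high_positive", 5))
})
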