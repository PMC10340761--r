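test_that("Mann-Whitney matches exact enumeration on separable groups", {
  # {1,2,3} vs {4,5,6}: U = 0 and the exact two-sided p is 2/C(6,3) = 0.1
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")
  # identical multisets carry no signal
  mw0 <- mann_whitney(c(1, 1, 2), c(2, 1, 1))
  expect_equal(mw0$p, 1)
  # constant data degenerates with a warning rather than NaN
  expect_warning(mwc <- mann_whitney(c(2, 2, 2), c(2, 2)), "identical")
  expect_equal(mwc$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(1)
  x <- rlnorm(12); y <- rlnorm(15, 0.5)
  a <- mann_whitney(x, y)
  b <- mann_whitney(log(x), log(y))
  c <- mann_whitney(x^3, y^3)
  expect_equal(a$u, b$u)
  expect_equal(a$p, b$p)
  expect_equal(a$p, c$p)
})

test_that("BH adjustment reproduces the step-up arithmetic and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.001, 0.9)), c(0.002, 0.9))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))^2
    q <- bh_adjust(p)
    expect_true(all(q >= p))                  # never decreases
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= 0))  # monotone in the raw p order
  }
})

test_that("logistic slope agrees with a brute-force likelihood maximiser", {
  set.seed(3)
  x <- rnorm(30)
  y <- rbinom(30, 1, plogis(0.8 * x - 0.2))
  fit <- logistic_univariate(x, y)
  # iterated grid refinement of the 2-parameter log-likelihood
  ll <- function(b0, b1) sum(y * (b0 + b1 * x) - log1p(exp(b0 + b1 * x)))
  centre <- c(0, 0); width <- 8
  for (step in 1:8) {
    b0s <- seq(centre[1] - width, centre[1] + width, length.out = 41)
    b1s <- seq(centre[2] - width, centre[2] + width, length.out = 41)
    grid <- expand.grid(b0 = b0s, b1 = b1s)
    vals <- mapply(ll, grid$b0, grid$b1)
    centre <- as.numeric(grid[which.max(vals), ]); width <- width / 8
  }
  expect_equal(fit$beta, centre[2], tolerance = 1e-4)
  expect_false(fit$separated)
})

test_that("complete separation is flagged, not reported as a Wald p-value", {
  x <- c(1:6, 11:16)
  y <- rep(c(0, 1), each = 6)
  fit <- logistic_univariate(x, y)
  expect_true(fit$separated)
  expect_true(is.na(fit$p))
})

test_that("marker screening reports medians, tests and per-family FDR", {
  cohort <- simulate_cohort(tiny_config(seed = 21))
  res <- screen_markers(cohort)
  expect_s3_class(res, "marker_screen")
  expect_equal(res$marker, c("CA9", "MIR125B1"))
  met <- cohort$outcome == "met"
  expect_equal(res$median_met[1], median(cohort$CA9[met]))
  expect_equal(res$n_met, c(31L, 31L))
  # each marker is its own modality family here, so adjustment is identity
  expect_equal(res$p_mw_adjusted, res$p_mw_raw)
  # global family of two: BH over both
  resg <- screen_markers(cohort, fdr_family = "global")
  expect_equal(resg$p_mw_adjusted, bh_adjust(res$p_mw_raw))
  expect_true(all(res$u_statistic >= 0 & res$u_statistic <= 31 * 49))
})

test_that("U statistic and empirical AUC are dual on tie-free data", {
  cohort <- simulate_cohort(tiny_config(seed = 22))
  res <- screen_markers(cohort)
  met <- cohort$outcome == "met"
  for (m in c("CA9", "MIR125B1")) {
    dir <- if (m == "CA9") "low_positive" else "high_positive"
    roc <- marker_roc(cohort[[m]], cohort$outcome, dir, marker = m)
    u <- res$u_statistic[res$marker == m]
    u_fav <- if (dir == "low_positive") 31 * 49 - u else u
    expect_equal(roc$auc, u_fav / (31 * 49), tolerance = 1e-12)
  }
})

test_that("markers that are mostly missing are dropped with a warning", {
  cohort <- simulate_cohort(tiny_config(seed = 23))
  cohort$CA9[1:60] <- NA
  expect_warning(res <- screen_markers(cohort), "CA9")
  expect_equal(res$marker, "MIR125B1")
})
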