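#' Empirical ROC analysis of one marker
#'
#' Builds the empirical ROC curve of a marker against the metastasis label,
#' computes the AUC with a DeLong confidence interval and a two-sided test
#' against AUC = 0.5, and selects the optimal cutoff by the Youden index.
#'
#' The direction is fixed a priori by marker modality rather than inferred
#' from the data: `low_positive` (expression) scores a sample positive when
#' its value is at or below the threshold, `high_positive` (methylation) when
#' strictly above. Thresholds are placed at observed values, so the reported
#' cutoff rule reads "<= v" or "> v" with v a data value. Youden ties are
#' broken toward the higher specificity.
#'
#' @param values Numeric marker values (missing values dropped pairwise).
#' @param outcome Binary labels; a factor with positive class `"met"` as its
#'   second level, or logical/0-1.
#' @param direction `"low_positive"` or `"high_positive"`.
#' @param conf_level Confidence level of the DeLong interval (default 0.95).
#' @param marker Optional marker name carried into the result.
#' @return An object of class `"marker_roc"`: list with `marker`,
#'   `direction`, `points` (data frame `threshold`, `fpr`, `tpr`), `auc`,
#'   `auc_se`, `auc_ci_low`, `auc_ci_high`, `p_vs_half`, `cutoff`,
#'   `cutoff_rule`, `sensitivity`, `specificity` (percent), `youden_j`,
#'   `n_pos`, `n_neg`.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 2))
#' marker_roc(cohort$CA9, cohort$outcome, "low_positive", marker = "CA9")
#' @export
marker_roc <- function(values, outcome,
                       direction = c("low_positive", "high_positive"),
                       conf_level = 0.95, marker = NULL) {
  direction <- match.arg(direction)
  y <- as_binary_outcome(outcome)
  keep <- !is.na(values) & !is.na(y)
  v <- values[keep]; y <- y[keep]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")

  # score scale: larger score = more positive; "score >= s" at an observed
  # score s is exactly "value <= v" (low_positive) or "value > v'" where v'
  # is the next lower observed value (high_positive)
  s <- if (direction == "low_positive") -v else v
  pos <- v[y == 1L]; neg <- v[y == 0L]

  thr_values <- sort(unique(v))
  if (direction == "low_positive") {
    cand <- thr_values                       # rule: value <= t
    tp <- vapply(cand, function(t) sum(pos <= t), numeric(1))
    fp <- vapply(cand, function(t) sum(neg <= t), numeric(1))
    sentinel <- -Inf                         # nothing called positive
  } else {
    cand <- c(sort(thr_values, decreasing = TRUE))  # rule: value > t
    tp <- vapply(cand, function(t) sum(pos > t), numeric(1))
    fp <- vapply(cand, function(t) sum(neg > t), numeric(1))
    sentinel <- -Inf                         # value > -Inf: all positive
  }
  # assemble monotone curve from (0,0) to (1,1)
  if (direction == "low_positive") {
    points <- data.frame(threshold = c(-Inf, cand),
                         fpr = c(0, fp) / n0, tpr = c(0, tp) / n1)
  } else {
    points <- data.frame(threshold = c(cand, sentinel),
                         fpr = c(fp, n0) / n0, tpr = c(tp, n1) / n1)
  }

  auc <- trapezoid_auc(points$fpr, points$tpr)
  dl <- delong_variance(pos, neg, direction)
  se <- sqrt(dl)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (se == 0) {
    if (auc %in% c(0, 1))
      warning("degenerate ROC (AUC = ", auc, "); confidence interval clipped")
    ci <- c(auc, auc)
    p_half <- if (auc == 0.5) 1 else 0
  } else {
    ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
    p_half <- 2 * stats::pnorm(-abs(auc - 0.5) / se)
  }

  # Youden over observed thresholds only, ties toward higher specificity;
  # J compared on the integer scale tp*n0 - fp*n1 so exact ties are exact
  j_int <- tp * n0 - fp * n1
  best <- which(j_int == max(j_int))
  if (length(best) > 1L) best <- best[which.min(fp[best])]
  cutoff <- cand[best]
  sens_pct <- 100 * tp[best] / n1
  spec_pct <- 100 * (n0 - fp[best]) / n0

  structure(list(
    marker = marker, direction = direction, points = points,
    auc = auc, auc_se = se, auc_ci_low = ci[1], auc_ci_high = ci[2],
    p_vs_half = p_half,
    cutoff = cutoff,
    cutoff_rule = sprintf(if (direction == "low_positive") "<= %g" else "> %g", cutoff),
    sensitivity = sens_pct, specificity = spec_pct,
    youden_j = sens_pct / 100 + spec_pct / 100 - 1,
    n_pos = n1, n_neg = n0
  ), class = "marker_roc")
}

as_binary_outcome <- function(outcome) {
  if (is.factor(outcome)) {
    if (nlevels(outcome) != 2L) stop("outcome factor must have two levels")
    as.integer(outcome) - 1L
  } else if (is.logical(outcome)) {
    as.integer(outcome)
  } else {
    o <- as.integer(outcome)
    if (!all(o %in% c(0L, 1L) | is.na(o))) stop("outcome must be binary")
    o
  }
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
}

# DeLong variance of the empirical AUC via placement values
delong_variance <- function(pos, neg, direction) {
  sp <- if (direction == "low_positive") -pos else pos
  sn <- if (direction == "low_positive") -neg else neg
  psi <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)   # placement of each positive among negatives
  v01 <- colMeans(psi)
  n1 <- length(sp); n0 <- length(sn)
  s10 <- if (n1 > 1) stats::var(v10) else 0
  s01 <- if (n0 > 1) stats::var(v01) else 0
  s10 / n1 + s01 / n0
}

#' @export
print.marker_roc <- function(x, ...) {
  cat("ROC analysis", if (!is.null(x$marker)) paste0(" of ", x$marker), "\n", sep = "")
  cat(sprintf("  direction : %s (positive when value %s)\n", x$direction,
              x$cutoff_rule))
  cat(sprintf("  AUC       : %.3f  (%d%% CI %.3f-%.3f, p vs 0.5 = %s)\n",
              x$auc, 95L, x$auc_ci_low, x$auc_ci_high, format.pval(x$p_vs_half, digits = 3)))
  cat(sprintf("  cutoff    : %s  (sens %.2f%%, spec %.2f%%, Youden J = %.3f)\n",
              x$cutoff_rule, x$sensitivity, x$specificity, x$youden_j))
  cat(sprintf("  samples   : %d positive / %d negative\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.marker_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = if (is.null(x$marker)) "ROC" else paste("ROC:", x$marker),
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}

#' ROC summary table over all markers of a cohort
#'
#' Runs [marker_roc()] for every registered marker with the
#' modality-appropriate direction and collects the headline quantities in one
#' table (one row per marker), mirroring the layout of a per-marker ROC
#' report: AUC, confidence interval, cutoff rule, sensitivity and
#' specificity.
#'
#' @inheritParams screen_markers
#' @param conf_level Confidence level of the DeLong intervals.
#' @return Data frame with columns `marker`, `modality`, `auc`, `auc_ci_low`,
#'   `auc_ci_high`, `p_vs_half`, `cutoff`, `cutoff_rule`, `sensitivity`,
#'   `specificity`, `youden_j`. The full `marker_roc` objects are attached as
#'   the `"rocs"` attribute.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 2))
#' roc_summary(cohort)[, c("marker", "auc", "cutoff_rule")]
#' @export
roc_summary <- function(cohort, registry = NULL, conf_level = 0.95) {
  if (!"outcome" %in% names(cohort)) stop("cohort lacks an 'outcome' column")
  registry <- resolve_registry(cohort, registry)
  rocs <- lapply(names(registry), function(m)
    marker_roc(cohort[[m]], cohort$outcome, modality_direction(registry[[m]]),
               conf_level = conf_level, marker = m))
  out <- do.call(rbind, lapply(rocs, function(r)
    data.frame(marker = r$marker, modality = NA_character_,
               auc = r$auc, auc_ci_low = r$auc_ci_low,
               auc_ci_high = r$auc_ci_high, p_vs_half = r$p_vs_half,
               cutoff = r$cutoff, cutoff_rule = r$cutoff_rule,
               sensitivity = r$sensitivity, specificity = r$specificity,
               youden_j = r$youden_j, stringsAsFactors = FALSE)))
  out$modality <- unname(registry[out$marker])
  attr(out, "rocs") <- stats::setNames(rocs, out$marker)
  out
}
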