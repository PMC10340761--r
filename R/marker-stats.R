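#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum test of a location difference between the metastatic
#' and non-metastatic values of a marker. Thin wrapper around
#' [stats::wilcox.test()] that fixes the conventions used throughout the
#' package: the returned `u` counts pairs in which a group-1 value exceeds a
#' group-0 value (ties half), and `mode = "auto"` uses the exact null
#' distribution when the smaller group has at most 8 observations and there
#' are no ties, otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param values_group1,values_group0 Numeric vectors (e.g. metastatic vs
#'   non-metastatic marker values), both non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return List with `u`, `p` (two-sided), `method`, and the group sizes
#'   `n1`, `n0`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p  # exact: 0.1
#' @export
mann_whitney <- function(values_group1, values_group0,
                         mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  x <- values_group1[!is.na(values_group1)]
  y <- values_group0[!is.na(values_group0)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0L
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(list(u = length(x) * length(y) / 2, p = 1,
                method = "degenerate", n1 = length(x), n0 = length(y)))
  }
  exact <- switch(mode,
                  exact = TRUE,
                  normal_approx = FALSE,
                  auto = min(length(x), length(y)) <= 8 && !ties)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(u = unname(wt$statistic), p = wt$p.value,
       method = if (exact && !ties) "exact" else "normal_approx",
       n1 = length(x), n0 = length(y))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values to control the false discovery rate, in the
#' input order, via [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Univariate logistic regression of outcome on one marker
#'
#' Fits `outcome ~ value` by maximum likelihood (IRLS via [stats::glm()]) and
#' returns the slope and its two-sided Wald p-value. Complete or
#' quasi-complete separation (fitted probabilities collapsing to 0/1, slope
#' diverging) is flagged; in that case the p-value is returned as `NA`
#' rather than a meaningless number.
#'
#' @param values Numeric marker values (apply any scale transform, e.g. log2
#'   for RQ, before calling).
#' @param outcome Binary labels: logical, 0/1, or a factor whose second level
#'   is the positive class.
#' @return List with `beta` (slope), `se`, `p` (Wald, two-sided), and
#'   `separated` (logical).
#' @examples
#' set.seed(1)
#' x <- rnorm(60); y <- rbinom(60, 1, plogis(x))
#' logistic_univariate(x, y)$beta
#' @export
logistic_univariate <- function(values, outcome) {
  y <- if (is.factor(outcome)) as.integer(outcome) - 1L else as.integer(outcome)
  keep <- !is.na(values) & !is.na(y)
  x <- values[keep]; y <- y[keep]
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  if (!all(is.finite(x))) stop("marker values must be finite")
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  co <- summary(fit)$coefficients
  beta <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
  separated <- sep_warned && (abs(beta) > 10 || se > 100)
  list(beta = beta, se = se,
       p = if (separated) NA_real_ else co["x", "Pr(>|z|)"],
       separated = separated)
}

#' Screen all markers of a cohort for association with metastasis
#'
#' For each marker: group medians, Mann-Whitney U test (two-sided,
#' `mode = "auto"`), Benjamini-Hochberg adjustment, and univariate logistic
#' regression (expression markers on the log2 scale, methylation on raw
#' percent). BH is applied within each FDR family; the default families are
#' the two modalities (expression markers adjusted together, methylation
#' markers together), `"global"` adjusts all markers as one family. Markers
#' with more than 50% missing values are dropped with a warning; within a
#' marker, missing values are removed pairwise.
#'
#' @param cohort A `cohort_table` with an `outcome` column (`nonmet`/`met`).
#' @param registry Named modality vector; defaults to the cohort's
#'   `"modality"` attribute, falling back to [default_marker_registry()].
#' @param fdr_family `"by_modality"` (default) or `"global"`.
#' @return A `marker_screen` data frame: `marker`, `modality`,
#'   `median_nonmet`, `median_met`, `n_nonmet`, `n_met`, `u_statistic`,
#'   `p_mw_raw`, `p_mw_adjusted`, `p_logit`, `logit_separated`.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 3))
#' screen_markers(cohort)
#' @export
screen_markers <- function(cohort, registry = NULL,
                           fdr_family = c("by_modality", "global")) {
  fdr_family <- match.arg(fdr_family)
  if (!"outcome" %in% names(cohort)) stop("cohort lacks an 'outcome' column")
  registry <- resolve_registry(cohort, registry)
  markers <- names(registry)
  met <- cohort$outcome == "met"

  keep <- vapply(markers, function(m) {
    ok <- mean(is.na(cohort[[m]])) <= 0.5
    if (!ok) warning("marker '", m, "' has >50% missing values; excluded")
    ok
  }, logical(1))
  markers <- markers[keep]
  if (!length(markers)) stop("no marker with sufficient data")

  rows <- lapply(markers, function(m) {
    v <- cohort[[m]]
    mw <- mann_whitney(v[met], v[!met])
    xv <- if (registry[[m]] == "expression") log2(v) else v
    lg <- logistic_univariate(xv[!is.na(v)], met[!is.na(v)])
    data.frame(
      marker = m, modality = registry[[m]],
      median_nonmet = stats::median(v[!met], na.rm = TRUE),
      median_met = stats::median(v[met], na.rm = TRUE),
      n_nonmet = sum(!met & !is.na(v)), n_met = sum(met & !is.na(v)),
      u_statistic = mw$u, p_mw_raw = mw$p, p_mw_adjusted = NA_real_,
      p_logit = lg$p, logit_separated = lg$separated,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  fam <- if (fdr_family == "global") rep("all", nrow(res)) else res$modality
  for (f in unique(fam))
    res$p_mw_adjusted[fam == f] <- bh_adjust(res$p_mw_raw[fam == f])
  class(res) <- c("marker_screen", "data.frame")
  res
}

resolve_registry <- function(cohort, registry = NULL) {
  if (is.null(registry)) registry <- attr(cohort, "modality")
  if (is.null(registry)) {
    def <- default_marker_registry()
    registry <- def[names(def) %in% names(cohort)]
  }
  markers <- intersect(names(registry), names(cohort))
  if (!length(markers)) stop("no registered marker column found in cohort")
  unlist(registry[markers])
}

#' @export
print.marker_screen <- function(x, digits = 3, ...) {
  cat("Per-marker association screen (", nrow(x), " markers)\n\n", sep = "")
  out <- as.data.frame(x)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits)
  out$p_logit[x$logit_separated] <- "<separation>"
  print(out, row.names = FALSE, ...)
  invisible(x)
}
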