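#' Define a count-rule marker panel
#'
#' A panel is an ordered set of markers, each with an event direction and a
#' cutoff, plus the count threshold `k_events`: a sample is called high-risk
#' when at least `k_events` of its marker events fire. An expression event is
#' a value at or below the cutoff (inclusive); a methylation event a value
#' strictly above it.
#'
#' @param name Panel name.
#' @param markers Character vector of marker names.
#' @param directions `"low_positive"`/`"high_positive"` per marker (recycled
#'   from modality defaults if named registry entries exist).
#' @param cutoffs Numeric cutoffs, one per marker.
#' @param k_events Count threshold for a positive call, `1 <= k <= m`.
#' @return An object of class `"panel_definition"`.
#' @seealso [builtin_panels()], [count_panel()]
#' @examples
#' panel_definition("toy", c("CA9", "MIR137"),
#'                  c("low_positive", "high_positive"), c(51.3, 57.62), 1)
#' @export
panel_definition <- function(name, markers, directions, cutoffs, k_events) {
  m <- length(markers)
  stopifnot(length(directions) == m, length(cutoffs) == m)
  if (!all(directions %in% c("low_positive", "high_positive")))
    stop("directions must be 'low_positive' or 'high_positive'")
  if (!is.numeric(cutoffs) || any(!is.finite(cutoffs)))
    stop("cutoffs must be finite numerics")
  if (k_events < 1 || k_events > m)
    stop("k_events must lie between 1 and the number of markers")
  structure(list(name = name,
                 markers = data.frame(marker = markers, direction = directions,
                                      cutoff = cutoffs, stringsAsFactors = FALSE),
                 k_events = as.integer(k_events)),
            class = "panel_definition")
}

#' The three built-in prognostic panels
#'
#' Returns the panel definitions used in the reference study: `EXPR4` (the
#' four expression markers CA9, NDUFA4L2, EGLN3, BHLHE41; positive at >= 3
#' events), `METH5` (the five methylation markers MIR125B1, MIR137, MIR375,
#' MIR193A, MIR34BC; >= 4), and `COMBINED9` (all nine; >= 6). By default the
#' cutoffs are the published per-marker ROC cutoffs of
#' [reference_marker_table()]; pass a named numeric vector (e.g. Youden
#' cutoffs re-estimated on your cohort with [roc_summary()]) to override.
#'
#' @param cutoffs Named numeric vector of cutoffs covering the nine panel
#'   markers; defaults to the published values.
#' @return Named list of three [panel_definition()] objects.
#' @examples
#' builtin_panels()$COMBINED9
#' @export
builtin_panels <- function(cutoffs = NULL) {
  ref <- reference_marker_table()
  if (is.null(cutoffs))
    cutoffs <- stats::setNames(ref$cutoff, ref$marker)
  expr4 <- c("CA9", "NDUFA4L2", "EGLN3", "BHLHE41")
  meth5 <- c("MIR125B1", "MIR137", "MIR375", "MIR193A", "MIR34BC")
  missing <- setdiff(c(expr4, meth5), names(cutoffs))
  if (length(missing))
    stop("no cutoff supplied for marker(s): ", paste(missing, collapse = ", "))
  dirs <- modality_direction(stats::setNames(ref$modality, ref$marker))
  mk <- function(name, markers, k)
    panel_definition(name, markers, unname(dirs[markers]),
                     unname(cutoffs[markers]), k)
  list(EXPR4 = mk("EXPR4", expr4, 3),
       METH5 = mk("METH5", meth5, 4),
       COMBINED9 = mk("COMBINED9", c(expr4, meth5), 6))
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("Count-rule panel '%s': positive at >= %d of %d events\n",
              x$name, x$k_events, nrow(x$markers)))
  rules <- ifelse(x$markers$direction == "low_positive",
                  sprintf("<= %g", x$markers$cutoff),
                  sprintf("> %g", x$markers$cutoff))
  cat(paste0("  ", format(x$markers$marker), "  event when value ", rules,
             collapse = "\n"), "\n")
  invisible(x)
}

#' Binary event matrix of a panel on a cohort
#'
#' Evaluates each panel marker's event rule on each sample. Samples with a
#' missing value in any panel marker are excluded and counted.
#'
#' @param cohort A `cohort_table` (outcome column optional here).
#' @param panel A [panel_definition()].
#' @return Integer 0/1 matrix, one row per evaluable sample (rownames =
#'   sample ids), one column per marker; excluded sample ids in
#'   `attr(, "excluded")`.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 2))
#' ev <- call_events(cohort, builtin_panels()$EXPR4)
#' head(ev)
#' @export
call_events <- function(cohort, panel) {
  stopifnot(inherits(panel, "panel_definition"))
  absent <- setdiff(panel$markers$marker, names(cohort))
  if (length(absent))
    stop("panel marker(s) absent from cohort: ", paste(absent, collapse = ", "))
  vals <- as.matrix(cohort[, panel$markers$marker, drop = FALSE])
  complete <- stats::complete.cases(vals)
  excluded <- cohort$sample_id[!complete]
  vals <- vals[complete, , drop = FALSE]
  ev <- matrix(0L, nrow(vals), ncol(vals),
               dimnames = list(cohort$sample_id[complete], panel$markers$marker))
  for (j in seq_len(ncol(vals))) {
    ev[, j] <- if (panel$markers$direction[j] == "low_positive")
      as.integer(vals[, j] <= panel$markers$cutoff[j])
    else
      as.integer(vals[, j] > panel$markers$cutoff[j])
  }
  attr(ev, "excluded") <- as.character(excluded)
  ev
}

#' Classify samples by a k-of-m count rule
#'
#' @param events Binary event matrix (rows = samples).
#' @param k Count threshold; a sample is called positive when its row sum is
#'   at least `k`.
#' @return Data frame with `sample_id`, `count` (0..m ordinal score) and
#'   `call` (0/1).
#' @examples
#' ev <- rbind(a = c(1, 1, 1, 0), b = c(0, 1, 0, 0))
#' classify_count_rule(ev, 3)
#' @export
classify_count_rule <- function(events, k) {
  events <- as.matrix(events)
  if (!all(events %in% c(0, 1))) stop("events must be binary")
  if (k > ncol(events)) stop("k exceeds the number of markers")
  count <- as.integer(rowSums(events))
  data.frame(sample_id = if (is.null(rownames(events)))
               as.character(seq_len(nrow(events))) else rownames(events),
             count = count, call = as.integer(count >= k),
             stringsAsFactors = FALSE)
}

clopper_pearson <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  100 * as.numeric(stats::binom.test(x, n, conf.level = conf_level)$conf.int)
}

#' Diagnostic performance of a count-rule panel
#'
#' Confusion counts of the binary calls against the outcome, with
#' sensitivity, specificity, PPV and NPV in percent and exact
#' Clopper-Pearson 95% confidence intervals, plus the AUC of the ordinal
#' count score (trapezoidal over the thresholds 0..m), which measures how
#' well the raw event count ranks metastatic above non-metastatic samples.
#'
#' @param predictions Binary calls (0/1).
#' @param count_scores Ordinal event counts, same length.
#' @param outcome Binary labels (factor `nonmet`/`met`, logical, or 0/1).
#' @param n_excluded Number of samples excluded for missing panel markers
#'   (bookkeeping only).
#' @param panel_name Optional name carried into the result.
#' @param conf_level Confidence level of the Clopper-Pearson intervals.
#' @return An object of class `"panel_performance"`: list with the confusion
#'   counts `tp`, `fp`, `tn`, `fn`; `sensitivity`, `specificity`, `ppv`,
#'   `npv` (percent, `NA` when undefined) each with `*_ci` bounds;
#'   `auc_count_score`; `n_excluded_missing`.
#' @examples
#' perf <- panel_performance(c(1, 1, 0, 0), c(7, 6, 3, 2),
#'                           factor(c("met", "met", "nonmet", "nonmet"),
#'                                  c("nonmet", "met")))
#' perf$sensitivity
#' @export
panel_performance <- function(predictions, count_scores, outcome,
                              n_excluded = 0, panel_name = NULL,
                              conf_level = 0.95) {
  y <- as_binary_outcome(outcome)
  stopifnot(length(predictions) == length(y),
            length(count_scores) == length(y))
  if (!all(y %in% 0:1) || length(unique(y)) < 2L)
    stop("both outcome classes must be present")
  tp <- sum(predictions == 1 & y == 1); fp <- sum(predictions == 1 & y == 0)
  tn <- sum(predictions == 0 & y == 0); fn <- sum(predictions == 0 & y == 1)
  rate <- function(x, n) if (n == 0) NA_real_ else 100 * x / n
  ci <- function(x, n) if (n == 0) c(NA_real_, NA_real_)
        else clopper_pearson(x, n, conf_level)
  sens_ci <- ci(tp, tp + fn); spec_ci <- ci(tn, tn + fp)
  ppv_ci <- ci(tp, tp + fp); npv_ci <- ci(tn, tn + fn)
  auc <- count_score_auc(count_scores, y)
  structure(list(
    panel = panel_name, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = rate(tp, tp + fn), sensitivity_ci = sens_ci,
    specificity = rate(tn, tn + fp), specificity_ci = spec_ci,
    ppv = rate(tp, tp + fp), ppv_ci = ppv_ci,
    npv = rate(tn, tn + fn), npv_ci = npv_ci,
    auc_count_score = auc, n_excluded_missing = n_excluded,
    conf_level = conf_level
  ), class = "panel_performance")
}

# trapezoidal AUC of an ordinal score (higher = more positive)
count_score_auc <- function(score, y) {
  thr <- sort(unique(score))
  tpr <- c(1, vapply(thr, function(t) mean(score[y == 1] > t), numeric(1)))
  fpr <- c(1, vapply(thr, function(t) mean(score[y == 0] > t), numeric(1)))
  trapezoid_auc(fpr, tpr)
}

#' @export
print.panel_performance <- function(x, ...) {
  fmt <- function(v, ci) {
    if (is.na(v)) return("undefined (empty denominator)")
    sprintf("%.2f%% (%.2f-%.2f)", v, ci[1], ci[2])
  }
  cat("Panel performance", if (!is.null(x$panel)) paste0(": ", x$panel), "\n", sep = "")
  cat(sprintf("  confusion   : TP %d  FP %d  TN %d  FN %d (%d excluded, missing markers)\n",
              x$tp, x$fp, x$tn, x$fn, x$n_excluded_missing))
  cat("  sensitivity :", fmt(x$sensitivity, x$sensitivity_ci), "\n")
  cat("  specificity :", fmt(x$specificity, x$specificity_ci), "\n")
  cat("  PPV         :", fmt(x$ppv, x$ppv_ci), "\n")
  cat("  NPV         :", fmt(x$npv, x$npv_ci), "\n")
  cat(sprintf("  count-score AUC : %.3f\n", x$auc_count_score))
  invisible(x)
}

#' Reconstruct an integer confusion matrix from reported rates
#'
#' Given published sensitivity and specificity (percent) and the group sizes,
#' recovers the unique integer confusion matrix by rounding half-up, then
#' verifies that the re-derived rates round back (half-up, two decimals) to
#' the inputs; an inconsistent quadruple raises an error reporting both
#' values. This makes the internal arithmetic of a published performance
#' table checkable without the underlying data.
#'
#' @param sens_pct,spec_pct Reported rates in percent.
#' @param n_pos,n_neg Numbers of positive (metastatic) and negative samples.
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @examples
#' reconstruct_confusion(87.10, 95.92, 31, 49)  # tp 27, fp 2, tn 47, fn 4
#' @export
reconstruct_confusion <- function(sens_pct, spec_pct, n_pos, n_neg) {
  stopifnot(sens_pct >= 0, sens_pct <= 100, spec_pct >= 0, spec_pct <= 100,
            n_pos >= 1, n_neg >= 1)
  tp <- round_half_up(sens_pct * n_pos / 100)
  tn <- round_half_up(spec_pct * n_neg / 100)
  fn <- n_pos - tp; fp <- n_neg - tn
  back_sens <- round_half_up(100 * tp / n_pos, 2)
  back_spec <- round_half_up(100 * tn / n_neg, 2)
  if (back_sens != round_half_up(sens_pct, 2) ||
      back_spec != round_half_up(spec_pct, 2))
    stop(sprintf(paste0("inconsistent rates: sensitivity %.2f re-derives as %.2f, ",
                        "specificity %.2f as %.2f"),
                 sens_pct, back_sens, spec_pct, back_spec))
  c(tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn), fn = as.integer(fn))
}

#' Fit a count-rule panel on a cohort
#'
#' The panel model of this package: each marker is binarised into an event at
#' a direction-aware cutoff, and a sample is called high-risk when at least
#' `k` events fire. `count_panel()` fixes the cutoffs — either the published
#' reference cutoffs, explicit values, or Youden-optimal cutoffs re-estimated
#' on the cohort (`cutoffs = "auto"`) — evaluates the rule on the fitting
#' cohort, and returns a classed model object with the usual methods:
#' [print()], [summary()] (diagnostic performance), [coef()] (cutoffs),
#' [predict()] (calls on new data) and [plot()] (count-score ROC).
#'
#' @param cohort A `cohort_table` with an `outcome` column.
#' @param definition A [panel_definition()]; overrides `markers`/`cutoffs`.
#' @param markers Marker names (defaults to the nine combined-panel markers
#'   present in the cohort).
#' @param k Count threshold; defaults to `ceiling(2/3 * m)`, which reproduces
#'   the built-in rules 3-of-4, 4-of-5(≈) and 6-of-9.
#' @param cutoffs `"auto"` (Youden on this cohort), `"reference"` (published
#'   values), or a named numeric vector.
#' @param registry Named modality vector (see [screen_markers()]).
#' @param name Panel name.
#' @return An object of class `"count_panel"` with elements `definition`,
#'   `calls` (fitting-cohort calls), `performance`
#'   ([panel_performance()] on the fitting cohort) and `rocs` (per-marker
#'   [marker_roc()] fits when `cutoffs = "auto"`).
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 2))
#' fit <- count_panel(cohort, cutoffs = "reference")
#' summary(fit)
#' @export
count_panel <- function(cohort, definition = NULL, markers = NULL, k = NULL,
                        cutoffs = c("auto", "reference"), registry = NULL,
                        name = "panel") {
  if (!"outcome" %in% names(cohort)) stop("cohort lacks an 'outcome' column")
  rocs <- NULL
  if (is.null(definition)) {
    registry <- resolve_registry(cohort, registry)
    if (is.null(markers)) {
      markers <- intersect(builtin_panels()$COMBINED9$markers$marker, names(registry))
      if (!length(markers)) markers <- names(registry)
    }
    absent <- setdiff(markers, names(registry))
    if (length(absent))
      stop("unregistered marker(s): ", paste(absent, collapse = ", "))
    dirs <- modality_direction(unname(registry[markers]))
    if (is.character(cutoffs)) {
      cutoffs <- match.arg(cutoffs)
      if (cutoffs == "reference") {
        ref <- reference_marker_table()
        cut <- stats::setNames(ref$cutoff, ref$marker)[markers]
        if (anyNA(cut))
          stop("no reference cutoff for marker(s): ",
               paste(markers[is.na(cut)], collapse = ", "))
      } else {
        rocs <- lapply(seq_along(markers), function(i)
          marker_roc(cohort[[markers[i]]], cohort$outcome, dirs[i],
                     marker = markers[i]))
        cut <- stats::setNames(vapply(rocs, `[[`, numeric(1), "cutoff"), markers)
      }
    } else {
      absent <- setdiff(markers, names(cutoffs))
      if (length(absent))
        stop("no cutoff supplied for marker(s): ", paste(absent, collapse = ", "))
      cut <- cutoffs[markers]
    }
    if (is.null(k)) k <- ceiling(2 / 3 * length(markers))
    definition <- panel_definition(name, markers, dirs, unname(cut), k)
  }
  events <- call_events(cohort, definition)
  calls <- classify_count_rule(events, definition$k_events)
  idx <- match(calls$sample_id, cohort$sample_id)
  perf <- panel_performance(calls$call, calls$count, cohort$outcome[idx],
                            n_excluded = length(attr(events, "excluded")),
                            panel_name = definition$name)
  structure(list(definition = definition, events = events, calls = calls,
                 outcome = cohort$outcome[idx], performance = perf,
                 rocs = rocs),
            class = "count_panel")
}

#' @export
print.count_panel <- function(x, ...) {
  print(x$definition)
  cat(sprintf("Fitted on %d samples (%d excluded for missing markers): AUC of count score %.3f\n",
              nrow(x$calls), x$performance$n_excluded_missing,
              x$performance$auc_count_score))
  invisible(x)
}

#' @export
summary.count_panel <- function(object, ...) object$performance

#' @export
coef.count_panel <- function(object, ...)
  stats::setNames(object$definition$markers$cutoff, object$definition$markers$marker)

#' Predict metastasis risk calls on new samples
#'
#' @param object A fitted [count_panel()].
#' @param newdata A `cohort_table` (or data frame) containing the panel
#'   marker columns; defaults to the fitting cohort's calls.
#' @param ... Unused.
#' @return Data frame `sample_id`, `count`, `call`.
#' @export
predict.count_panel <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$calls)
  if (is.null(newdata$sample_id))
    newdata$sample_id <- as.character(seq_len(nrow(newdata)))
  events <- call_events(newdata, object$definition)
  classify_count_rule(events, object$definition$k_events)
}

#' @export
plot.count_panel <- function(x, ...) {
  thr <- 0:nrow(x$definition$markers)
  y <- as_binary_outcome(x$outcome)
  tpr <- c(1, vapply(thr, function(t) mean(x$calls$count[y == 1] > t), numeric(1)))
  fpr <- c(1, vapply(thr, function(t) mean(x$calls$count[y == 0] > t), numeric(1)))
  graphics::plot(fpr, tpr, type = "b", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("Count-score ROC: %s", x$definition$name), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$performance$auc_count_score))
  invisible(x)
}
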