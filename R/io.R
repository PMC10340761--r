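#' Read a cohort table from CSV
#'
#' Expects a header row with `sample_id`, optionally `outcome`, and one
#' numeric column per marker. The token `NA` (or an empty field) is a missing
#' marker value; any other unparseable numeric is an error naming the column.
#' Duplicate sample ids are rejected.
#'
#' @param path CSV file path.
#' @param registry Named modality vector for the marker columns; defaults to
#'   the intersection of the file's columns with
#'   [default_marker_registry()].
#' @param outcome_labels Length-2 named character vector mapping the file's
#'   outcome codes, `c(nonmet = ..., met = ...)`.
#' @return A `cohort_table` data frame.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort(simulate_cohort(sim_config(seed = 1)), f)
#' cohort <- read_cohort(f)
#' @export
read_cohort <- function(path, registry = NULL,
                        outcome_labels = c(nonmet = "nonmet", met = "met")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(raw)) stop("missing required column: sample_id")
  raw$sample_id <- as.character(raw$sample_id)
  dup <- unique(raw$sample_id[duplicated(raw$sample_id)])
  if (length(dup)) stop("duplicate sample_id: ", paste(dup, collapse = ", "))
  if ("outcome" %in% names(raw)) {
    unknown <- setdiff(unique(raw$outcome), outcome_labels)
    if (length(unknown))
      stop("unrecognised outcome label(s): ", paste(unknown, collapse = ", "))
    raw$outcome <- factor(names(outcome_labels)[match(raw$outcome, outcome_labels)],
                          levels = c("nonmet", "met"))
  }
  marker_cols <- setdiff(names(raw), c("sample_id", "outcome"))
  for (m in marker_cols) {
    if (is.character(raw[[m]])) {
      tok <- trimws(raw[[m]]); tok[tok %in% c("NA", "")] <- NA
      num <- suppressWarnings(as.numeric(tok))
      bad <- which(!is.na(tok) & is.na(num))
      if (length(bad))
        stop(sprintf("unparseable value '%s' in column '%s', row %d",
                     tok[bad[1]], m, bad[1]))
      raw[[m]] <- num
    }
  }
  if (is.null(registry)) {
    def <- default_marker_registry()
    registry <- def[names(def) %in% marker_cols]
  }
  attr(raw, "modality") <- unlist(registry)
  class(raw) <- c("cohort_table", "data.frame")
  raw
}

#' Write a cohort table to CSV
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read/write a long-format Ct table
#'
#' The long format has one row per reaction: `sample_id`, `assay`,
#' `reaction`, `ct`, with undetermined reactions stored as the token
#' `undetermined` (never coerced to a pseudo-cycle number).
#'
#' @param path CSV path.
#' @return `read_ct_table`: the long data frame with numeric `ct` (`NA` =
#'   undetermined).
#' @examples
#' sim <- simulate_ct_tables(sim_config(seed = 1, emit_raw_ct = TRUE))
#' f <- tempfile(fileext = ".csv")
#' write_ct_table(sim$ct, f)
#' ct <- read_ct_table(f)
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay", "reaction", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.character(ct$ct)) {
    tok <- trimws(ct$ct)
    tok[tolower(tok) %in% c("undetermined", "na", "")] <- NA
    num <- suppressWarnings(as.numeric(tok))
    bad <- which(!is.na(tok) & is.na(num))
    if (length(bad))
      stop(sprintf("unparseable Ct value '%s' in row %d", tok[bad[1]], bad[1]))
    ct$ct <- num
  }
  ct
}

#' @rdname read_ct_table
#' @param ct Long Ct data frame (`NA` ct = undetermined).
#' @export
write_ct_table <- function(ct, path) {
  out <- ct
  out$ct <- ifelse(is.na(out$ct), "undetermined", format(out$ct, digits = 15))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Ties the stages together: obtain a cohort (simulate one, read a wide
#' cohort CSV, or quantify a raw Ct CSV plus outcome labels), screen all
#' markers, run the per-marker ROC analysis, and evaluate the three built-in
#' count-rule panels. All artefacts are written under `out_dir`:
#' `cohort.csv`, `marker_stats.tsv`, `roc_summary.tsv`, one
#' `roc_<marker>.tsv` of curve points per marker, `panel_calls.csv`,
#' `panel_report.json` and a machine-readable `summary.json` (full precision;
#' rounding is left to human-readable reports).
#'
#' @param cohort A `cohort_table`, or `NULL` to use `cohort_csv`/`ct_csv`/
#'   `simulate`.
#' @param cohort_csv,ct_csv Input file paths (wide cohort, or long raw Ct).
#' @param outcome_csv Two-column CSV `sample_id,outcome` required with
#'   `ct_csv`.
#' @param simulate If `TRUE`, simulate the default reference-calibrated
#'   cohort with `seed`.
#' @param seed Seed for simulation.
#' @param out_dir Output directory (created if needed).
#' @param panel_cutoffs `"auto"` (Youden per marker on this cohort) or
#'   `"reference"` (published cutoffs) for the built-in panels.
#' @param fdr_family Passed to [screen_markers()].
#' @param qc_threshold Passed to [quantify_ct()].
#' @return Invisibly, a list with `cohort`, `screen`, `roc`, `panels`
#'   (list of [count_panel()] fits) and `summary` (the content of
#'   `summary.json`).
#' @examples
#' \donttest{
#' bundle <- run_full_pipeline(simulate = TRUE, seed = 1, out_dir = tempfile())
#' names(bundle)
#' }
#' @export
run_full_pipeline <- function(cohort = NULL, cohort_csv = NULL, ct_csv = NULL,
                              outcome_csv = NULL, simulate = FALSE, seed = 1,
                              out_dir = "metpanel_out",
                              panel_cutoffs = c("auto", "reference"),
                              fdr_family = c("by_modality", "global"),
                              qc_threshold = 35) {
  panel_cutoffs <- match.arg(panel_cutoffs)
  fdr_family <- match.arg(fdr_family)
  if (is.null(cohort)) {
    if (simulate) {
      cohort <- simulate_cohort(sim_config(seed = seed))
    } else if (!is.null(cohort_csv)) {
      cohort <- read_cohort(cohort_csv)
    } else if (!is.null(ct_csv)) {
      if (is.null(outcome_csv))
        stop("ct_csv input needs outcome_csv with sample_id,outcome")
      cohort <- quantify_ct(read_ct_table(ct_csv), qc_threshold = qc_threshold)
      lab <- utils::read.csv(outcome_csv, stringsAsFactors = FALSE)
      idx <- match(cohort$sample_id, lab$sample_id)
      if (anyNA(idx)) stop("outcome labels missing for some samples")
      cohort$outcome <- factor(lab$outcome[idx], levels = c("nonmet", "met"))
    } else {
      stop("provide a cohort, an input file, or simulate = TRUE")
    }
  }
  if (!"outcome" %in% names(cohort)) stop("cohort lacks an 'outcome' column")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  screen <- screen_markers(cohort, fdr_family = fdr_family)
  utils::write.table(as.data.frame(screen), file.path(out_dir, "marker_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  roc <- roc_summary(cohort)
  utils::write.table(roc[, setdiff(names(roc), "rocs")],
                     file.path(out_dir, "roc_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (r in attr(roc, "rocs"))
    utils::write.table(r$points, file.path(out_dir, sprintf("roc_%s.tsv", r$marker)),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  cuts <- if (panel_cutoffs == "auto")
    stats::setNames(roc$cutoff, roc$marker) else NULL
  defs <- builtin_panels(cutoffs = cuts)
  panels <- lapply(defs, function(d) count_panel(cohort, definition = d))

  calls <- do.call(rbind, lapply(names(panels), function(nm)
    cbind(panel = nm, panels[[nm]]$calls)))
  utils::write.csv(calls, file.path(out_dir, "panel_calls.csv"), row.names = FALSE)

  perf_list <- lapply(panels, function(p) {
    pf <- p$performance
    list(tp = pf$tp, fp = pf$fp, tn = pf$tn, fn = pf$fn,
         sensitivity = pf$sensitivity, sensitivity_ci = pf$sensitivity_ci,
         specificity = pf$specificity, specificity_ci = pf$specificity_ci,
         ppv = pf$ppv, ppv_ci = pf$ppv_ci, npv = pf$npv, npv_ci = pf$npv_ci,
         auc_count_score = pf$auc_count_score,
         n_excluded_missing = pf$n_excluded_missing)
  })
  jsonlite::write_json(perf_list, file.path(out_dir, "panel_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  summary <- list(
    n_samples = nrow(cohort),
    n_met = sum(cohort$outcome == "met"),
    n_nonmet = sum(cohort$outcome == "nonmet"),
    markers = as.data.frame(screen),
    roc = roc[, setdiff(names(roc), "rocs")],
    panels = perf_list
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, screen = screen, roc = roc,
                 panels = panels, summary = summary))
}
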