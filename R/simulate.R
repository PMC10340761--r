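#' Specification of one simulated marker
#'
#' Describes how to draw one marker in a synthetic case-control cohort.
#' Expression markers are drawn log-normal, parameterised by the group median
#' (the exponential of the log-mean) and a log-scale standard deviation;
#' methylation markers are drawn from a Beta distribution rescaled to
#' \[0, 100\], with the location parameter solved numerically so the
#' distribution median equals the configured median at the given
#' concentration.
#'
#' @param name Marker identifier (unique within a configuration).
#' @param modality `"expression"` or `"methylation"`.
#' @param median_nonmet,median_met Group medians: positive RQ for expression,
#'   percent strictly inside (0, 100) for methylation.
#' @param dispersion Log-scale standard deviation (expression) or Beta
#'   concentration, i.e. the sum of the two shape parameters (methylation).
#'   Must be positive.
#' @return An object of class `"marker_sim_spec"`.
#' @seealso [default_marker_specs()], [sim_config()]
#' @examples
#' marker_sim_spec("CA9", "expression", 92.7, 17.8, 1.45)
#' @export
marker_sim_spec <- function(name, modality = c("expression", "methylation"),
                            median_nonmet, median_met, dispersion) {
  modality <- match.arg(modality)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("marker name must be a non-empty string")
  bad <- function(msg) stop(sprintf("marker '%s': %s", name, msg), call. = FALSE)
  if (!is.numeric(dispersion) || length(dispersion) != 1L ||
      !is.finite(dispersion) || dispersion <= 0)
    bad("dispersion must be a positive number")
  for (m in c(median_nonmet, median_met)) {
    if (!is.numeric(m) || length(m) != 1L || !is.finite(m)) bad("medians must be finite")
    if (modality == "expression" && m <= 0)
      bad("expression medians must be > 0")
    if (modality == "methylation" && (m <= 0 || m >= 100))
      bad("methylation medians must lie strictly inside (0, 100)")
  }
  structure(list(name = name, modality = modality,
                 median_nonmet = median_nonmet, median_met = median_met,
                 dispersion = dispersion),
            class = "marker_sim_spec")
}

#' Default simulation specs calibrated to the reference cohort
#'
#' One spec per study marker, with group medians taken from
#' [reference_marker_table()]. Dispersions are fixed package constants,
#' calibrated once so that the large-sample single-marker AUC between groups
#' matches the reference ROC table: for a log-normal marker with common
#' log-sd `s`, AUC = pnorm(log(m0/m1) / (s * sqrt(2))), which is solved in
#' closed form; for Beta methylation markers the concentration is solved
#' numerically from the same AUC identity. The three miRNA markers without a
#' reported AUC use the median concentration of the significant miRNAs.
#'
#' @return Named list of [marker_sim_spec()] objects.
#' @examples
#' names(default_marker_specs())
#' @export
default_marker_specs <- function() {
  ref <- reference_marker_table()
  disp <- c(CA9 = 1.4531880, NDUFA4L2 = 1.9066162, EGLN3 = 1.0936406,
            BHLHE41 = 0.7232883,
            MIR125B1 = 5.215393, MIR137 = 3.241258, MIR375 = 2.312295,
            MIR193A = 3.832197, MIR34BC = 3.668844, MIR1258 = 19.938930,
            MIR107 = 3.67, MIR203A = 3.67, MIR132 = 3.67)
  specs <- lapply(seq_len(nrow(ref)), function(i)
    marker_sim_spec(ref$marker[i], ref$modality[i],
                    ref$median_nonmet[i], ref$median_met[i],
                    unname(disp[ref$marker[i]])))
  stats::setNames(specs, ref$marker)
}

#' Configuration of a synthetic cohort
#'
#' @param markers List of [marker_sim_spec()] objects; defaults to the
#'   thirteen study markers of [default_marker_specs()].
#' @param n_metastatic,n_nonmetastatic Group sizes; the defaults (31 and 49)
#'   are the reference cohort's.
#' @param seed Integer seed; fully determines the simulated tables.
#' @param emit_raw_ct If `TRUE`, [simulate_ct_tables()] may be used to emit a
#'   raw cycle-threshold table that quantifies back to the simulated values.
#' @return An object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(seed = 7)
#' @export
sim_config <- function(markers = default_marker_specs(),
                       n_metastatic = 31, n_nonmetastatic = 49,
                       seed = 1, emit_raw_ct = FALSE) {
  if (inherits(markers, "marker_sim_spec")) markers <- list(markers)
  if (!length(markers) || !all(vapply(markers, inherits, TRUE, "marker_sim_spec")))
    stop("markers must be a non-empty list of marker_sim_spec objects")
  nm <- vapply(markers, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicate marker names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  for (n in c(n_metastatic, n_nonmetastatic))
    if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
      stop("group sizes must be integers >= 1")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a finite number")
  structure(list(markers = stats::setNames(markers, nm),
                 n_metastatic = as.integer(n_metastatic),
                 n_nonmetastatic = as.integer(n_nonmetastatic),
                 seed = as.integer(seed),
                 emit_raw_ct = isTRUE(emit_raw_ct)),
            class = "sim_config")
}

# deterministic per-marker substream seed, so adding a marker never perturbs
# the draws of another
marker_substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) + 1000003 * h) %% 2147483647)
}

# Beta location mu such that qbeta(0.5, mu*k, (1-mu)*k) == q
beta_mu_for_median <- function(q, concentration) {
  # qbeta warns about accuracy at the extreme bracket endpoints; the root
  # itself is interior, so those evaluations only steer the bisection
  stats::uniroot(function(mu)
    suppressWarnings(stats::qbeta(0.5, mu * concentration, (1 - mu) * concentration)) - q,
    c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

# dynamic range of a 45-cycle qPCR assay: differences of more than 24 cycles
# between two reactions are not resolvable, so simulated values are clipped
# to the corresponding RQ / MI range
ct_dynamic_range <- 24

draw_marker <- function(spec, n_nonmet, n_met, seed) {
  set.seed(marker_substream_seed(seed, spec$name))
  if (spec$modality == "expression") {
    v0 <- stats::rlnorm(n_nonmet, log(spec$median_nonmet), spec$dispersion)
    v1 <- stats::rlnorm(n_met, log(spec$median_met), spec$dispersion)
    v <- pmin(pmax(c(v0, v1), 2^-20), 2^20)
  } else {
    k <- spec$dispersion
    mu0 <- beta_mu_for_median(spec$median_nonmet / 100, k)
    mu1 <- beta_mu_for_median(spec$median_met / 100, k)
    v0 <- 100 * stats::rbeta(n_nonmet, mu0 * k, (1 - mu0) * k)
    v1 <- 100 * stats::rbeta(n_met, mu1 * k, (1 - mu1) * k)
    mi_floor <- 100 * 2^-ct_dynamic_range / (1 + 2^-ct_dynamic_range)
    v <- pmin(pmax(c(v0, v1), mi_floor), 100 - mi_floor)
  }
  v
}

#' Simulate a synthetic case-control cohort
#'
#' Draws a per-sample marker matrix with the group structure fixed by the
#' configuration: non-metastatic samples first, then metastatic. Each marker
#' uses its own deterministic random substream derived from the global seed
#' and the marker name, so cohorts are reproducible and markers independent.
#'
#' @param config A [sim_config()].
#' @return A `cohort_table`: data frame with `sample_id`, `outcome` (factor
#'   with levels `nonmet`, `met`) and one numeric column per marker, carrying
#'   the marker modality registry in `attr(, "modality")`.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 7))
#' table(cohort$outcome)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n0 <- config$n_nonmetastatic; n1 <- config$n_metastatic
  out <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n0 + n1)),
    outcome = factor(rep(c("nonmet", "met"), c(n0, n1)),
                     levels = c("nonmet", "met")),
    stringsAsFactors = FALSE
  )
  for (spec in config$markers)
    out[[spec$name]] <- draw_marker(spec, n0, n1, config$seed)
  attr(out, "modality") <- vapply(config$markers, `[[`, "", "modality")
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Emit raw Ct tables that quantify back to a simulated cohort
#'
#' Inverts the quantification equations for every simulated marker value. For
#' an expression RQ the four-cycle quadruple uses fixed anchors (reference Ct
#' 20 in both tissues, target Ct 24 in normal tissue), so only the
#' delta-delta-Ct carries information: `ct_target_tumor = 24 - log2(RQ)`. For
#' a methylation index the stronger of the methylated/unmethylated pair is
#' anchored at 20 cycles with `ct_unmeth - ct_meth = log2(MI / (100 - MI))`,
#' keeping both reactions inside the 45-cycle window; an MI of exactly
#' 0 or 100 is emitted as an undetermined reaction on the silent channel. The
#' ACTB unconverted-template control is emitted as undetermined (no
#' amplification) for every sample, i.e. all samples pass conversion QC.
#'
#' @param config A [sim_config()] with `emit_raw_ct = TRUE`.
#' @return List with `cohort` (the simulated [simulate_cohort()] table) and
#'   `ct` (long data frame: `sample_id`, `assay`, `reaction`, `ct`, where `ct`
#'   is `NA` for an undetermined reaction).
#' @examples
#' sim <- simulate_ct_tables(sim_config(seed = 1, emit_raw_ct = TRUE))
#' head(sim$ct)
#' @export
simulate_ct_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!config$emit_raw_ct)
    stop("set emit_raw_ct = TRUE in the configuration to emit Ct tables")
  cohort <- simulate_cohort(config)
  modality <- attr(cohort, "modality")
  rows <- vector("list", length(config$markers) + 1L)
  for (i in seq_along(config$markers)) {
    spec <- config$markers[[i]]
    v <- cohort[[spec$name]]
    if (spec$modality == "expression") {
      rows[[i]] <- data.frame(
        sample_id = rep(cohort$sample_id, each = 4L),
        assay = spec$name,
        reaction = rep(c("target_tumor", "ref_tumor", "target_normal", "ref_normal"),
                       length(v)),
        ct = as.vector(rbind(24 - log2(v), 20, 24, 20)),
        stringsAsFactors = FALSE
      )
    } else {
      # anchor the stronger reaction at 20 cycles so the weaker one stays
      # inside the 45-cycle window for any value within the dynamic range
      lr <- ifelse(v <= 0 | v >= 100, NA_real_, log2(v / (100 - v)))
      ct_m <- ifelse(v == 0, NA_real_, ifelse(v == 100, 20, 20 + pmax(0, -lr)))
      ct_u <- ifelse(v == 100, NA_real_, ifelse(v == 0, 20, 20 + pmax(0, lr)))
      rows[[i]] <- data.frame(
        sample_id = rep(cohort$sample_id, each = 2L),
        assay = spec$name,
        reaction = rep(c("meth", "unmeth"), length(v)),
        ct = as.vector(rbind(ct_m, ct_u)),
        stringsAsFactors = FALSE
      )
    }
  }
  rows[[length(rows)]] <- data.frame(
    sample_id = cohort$sample_id, assay = "ACTB",
    reaction = "actb_unconverted", ct = NA_real_,
    stringsAsFactors = FALSE
  )
  ct <- do.call(rbind, rows)
  ct <- ct[order(match(ct$sample_id, cohort$sample_id)), , drop = FALSE]
  rownames(ct) <- NULL
  list(cohort = cohort, ct = ct)
}
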