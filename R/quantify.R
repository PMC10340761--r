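#' Relative expression from a delta-delta-Ct quadruple
#'
#' Computes RQ = eff^(-ddCt) with
#' ddCt = (Ct_target - Ct_ref)_tumor - (Ct_target - Ct_ref)_normal,
#' i.e. target expression in tumour tissue relative to paired normal tissue,
#' normalised to the reference gene (GAPDH in the study assays). All
#' arguments are vectorised; an undetermined cycle threshold is encoded as
#' `NA` and propagates to an `NA` result.
#'
#' @param ct_target_tumor,ct_ref_tumor,ct_target_normal,ct_ref_normal Cycle
#'   thresholds (PCR cycles), `NA` when the reaction did not amplify.
#' @param efficiency Amplification efficiency per cycle; 2.0 (perfect
#'   doubling) unless assay-specific calibration says otherwise.
#' @return Numeric vector of RQ values (positive; 1 means no change).
#' @examples
#' rq_from_ct(25, 20, 24, 20)  # 0.5
#' rq_from_ct(22, 20, 24, 20)  # 4
#' @export
rq_from_ct <- function(ct_target_tumor, ct_ref_tumor,
                       ct_target_normal, ct_ref_normal, efficiency = 2) {
  ddct <- (ct_target_tumor - ct_ref_tumor) - (ct_target_normal - ct_ref_normal)
  efficiency^(-ddct)
}

#' Methylation index from a methylated/unmethylated reaction pair
#'
#' The methylation index MI is the percentage of methylated template:
#' MI = 100 * Q_M / (Q_M + Q_U) with Q = eff^(-Ct). A reaction that did not
#' amplify (`NA` Ct) contributes Q = 0, so MI is 0 when only the
#' unmethylated reaction amplifies and 100 when only the methylated one does;
#' both reactions undetermined yield a missing value. For finite Ct pairs MI
#' lies strictly inside (0, 100).
#'
#' @param ct_meth,ct_unmeth Cycle thresholds of the methylated-specific and
#'   unmethylated-specific reactions; `NA` = no amplification.
#' @param efficiency Amplification efficiency per cycle (default 2.0).
#' @return Numeric vector of methylation indices in \[0, 100\].
#' @examples
#' mi_from_ct(30, 30)  # 50
#' mi_from_ct(30, 28)  # 20
#' mi_from_ct(NA, 28)  # 0
#' @export
mi_from_ct <- function(ct_meth, ct_unmeth, efficiency = 2) {
  # work on the Ct difference, not raw efficiency^(-Ct), to stay stable at
  # high cycle numbers
  n <- max(length(ct_meth), length(ct_unmeth))
  ct_meth <- rep_len(ct_meth, n); ct_unmeth <- rep_len(ct_unmeth, n)
  r <- efficiency^(ct_unmeth - ct_meth)       # Q_M / Q_U
  mi <- 100 * r / (1 + r)
  mi[is.na(ct_meth) & !is.na(ct_unmeth)] <- 0
  mi[!is.na(ct_meth) & is.na(ct_unmeth)] <- 100
  mi[is.na(ct_meth) & is.na(ct_unmeth)] <- NA_real_
  mi
}

#' Bisulfite-conversion quality control
#'
#' A sample passes when the ACTB reaction specific to the *unconverted*
#' template shows no amplification: an undetermined Ct, or a Ct at or above
#' the threshold (late signal treated as background).
#'
#' @param ct_actb_unconverted Ct of the unconverted-template control reaction
#'   (`NA` = no amplification). Vectorised.
#' @param ct_threshold Cycle threshold above which amplification is treated
#'   as absent (default 35).
#' @return Logical vector, `TRUE` = conversion complete, sample usable.
#' @examples
#' conversion_qc(c(NA, 25, 38))  # TRUE FALSE TRUE
#' @export
conversion_qc <- function(ct_actb_unconverted, ct_threshold = 35) {
  is.na(ct_actb_unconverted) | ct_actb_unconverted >= ct_threshold
}

#' Quantify a long-format Ct table into a per-sample marker matrix
#'
#' Takes raw cycle-threshold records (one row per reaction) and produces the
#' wide cohort table of RQ and MI values downstream stages consume.
#' Expression assays need the four reactions `target_tumor`, `ref_tumor`,
#' `target_normal`, `ref_normal`; methylation assays the pair `meth`,
#' `unmeth`. Rows with reaction `actb_unconverted` are the per-sample
#' bisulfite-conversion control: samples failing [conversion_qc()] have all
#' their methylation values set to missing and are reported via the
#' `"qc_failed"` attribute (with a warning), matching the study rule that
#' incompletely converted samples are excluded from methylation statistics.
#'
#' @param ct Long data frame with columns `sample_id`, `assay`, `reaction`,
#'   `ct` (numeric, `NA` for undetermined; the text token `"undetermined"` is
#'   also accepted).
#' @param qc_threshold Passed to [conversion_qc()].
#' @param efficiency Amplification efficiency per cycle.
#' @return A `cohort_table` data frame (`sample_id` plus one column per
#'   assay) with the marker modality registry in `attr(, "modality")` and the
#'   ids of conversion-QC failures in `attr(, "qc_failed")`. No outcome
#'   column: labels are joined by the caller.
#' @examples
#' sim <- simulate_ct_tables(sim_config(seed = 1, emit_raw_ct = TRUE))
#' wide <- quantify_ct(sim$ct)
#' @export
quantify_ct <- function(ct, qc_threshold = 35, efficiency = 2) {
  need <- c("sample_id", "assay", "reaction", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.character(ct$ct)) {
    tok <- trimws(ct$ct)
    tok[tolower(tok) %in% c("undetermined", "na", "")] <- NA
    ct$ct <- suppressWarnings(as.numeric(tok))
    if (any(!is.na(tok) & is.na(ct$ct)))
      stop("unparseable Ct value(s): ",
           paste(utils::head(unique(tok[!is.na(tok) & is.na(ct$ct)]), 3), collapse = ", "))
  }
  bad <- !is.na(ct$ct) & (ct$ct <= 0 | ct$ct > 45)
  if (any(bad))
    stop("Ct values outside (0, 45] for sample(s): ",
         paste(utils::head(unique(ct$sample_id[bad]), 3), collapse = ", "))

  samples <- unique(ct$sample_id)
  pick <- function(d, reaction) {
    v <- d$ct[d$reaction == reaction]
    if (length(v) == 0L) NA_real_ else v[1L]
  }

  qc_ct <- ct[ct$reaction == "actb_unconverted", , drop = FALSE]
  qc_pass <- stats::setNames(rep(TRUE, length(samples)), samples)
  if (nrow(qc_ct)) {
    per <- tapply(qc_ct$ct, qc_ct$sample_id, function(v) all(conversion_qc(v, qc_threshold)))
    qc_pass[names(per)] <- as.logical(per)
  }
  qc_failed <- names(qc_pass)[!qc_pass]

  assays <- setdiff(unique(ct$assay), unique(ct$assay[ct$reaction == "actb_unconverted"]))
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  modality <- character(0)
  for (a in assays) {
    da <- ct[ct$assay == a, , drop = FALSE]
    reactions <- unique(da$reaction)
    is_expr <- any(reactions %in% c("target_tumor", "ref_tumor", "target_normal", "ref_normal"))
    is_meth <- any(reactions %in% c("meth", "unmeth"))
    if (is_expr && is_meth)
      stop("assay '", a, "' mixes expression and methylation reactions")
    if (!is_expr && !is_meth)
      stop("assay '", a, "' has unrecognised reactions: ",
           paste(reactions, collapse = ", "))
    vals <- vapply(samples, function(s) {
      d <- da[da$sample_id == s, , drop = FALSE]
      if (!nrow(d)) return(NA_real_)
      if (is_expr)
        rq_from_ct(pick(d, "target_tumor"), pick(d, "ref_tumor"),
                   pick(d, "target_normal"), pick(d, "ref_normal"), efficiency)
      else
        mi_from_ct(pick(d, "meth"), pick(d, "unmeth"), efficiency)
    }, numeric(1))
    if (is_meth) vals[samples %in% qc_failed] <- NA_real_
    out[[a]] <- unname(vals)
    modality[a] <- if (is_expr) "expression" else "methylation"
  }
  if (length(qc_failed))
    warning("bisulfite-conversion QC failed for ", length(qc_failed),
            " sample(s): ", paste(utils::head(qc_failed, 5), collapse = ", "),
            "; their methylation values were set to missing")
  attr(out, "modality") <- modality
  attr(out, "qc_failed") <- qc_failed
  class(out) <- c("cohort_table", "data.frame")
  out
}
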