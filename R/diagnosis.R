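#' Classify a subject's CSF profile as normal or abnormal
#'
#' A subject's cerebrospinal-fluid profile is *normal* if every available
#' observation satisfies both conditions: CSF amyloid-beta 1-42 at or above
#' the amyloid cut-off AND total tau at or below the tau cut-off (boundary
#' values count as normal). A single violating observation makes the profile
#' *abnormal*; with no observations at all the profile is *unknown*. The
#' default cut-offs (192 and 93 pg/mL) come from autopsy-validated ADNI
#' thresholds.
#'
#' @param abeta,tau Numeric vectors of CSF amyloid-beta 1-42 and total tau
#'   concentrations (pg/mL), aligned by observation; `NA` pairs are ignored.
#' @param abeta_cutoff,tau_cutoff Positive cut-offs in pg/mL.
#' @return One of `"normal"`, `"abnormal"`, `"unknown"`.
#' @examples
#' classify_csf_profile(247.23, 55.41)        # "normal"
#' classify_csf_profile(c(250, 180), c(60, 60)) # "abnormal"
#' @export
classify_csf_profile <- function(abeta, tau, abeta_cutoff = 192, tau_cutoff = 93) {
  if (abeta_cutoff <= 0 || tau_cutoff <= 0)
    stop_config("CSF cut-offs must be positive")
  if (length(abeta) != length(tau))
    stop_config("abeta and tau must have the same length")
  ok <- !is.na(abeta) & !is.na(tau)
  if (any(abeta[ok] < 0) || any(tau[ok] < 0))
    stop_config("CSF concentrations must be non-negative")
  if (!any(ok)) return("unknown")
  normal <- abeta[ok] >= abeta_cutoff & tau[ok] <= tau_cutoff
  if (all(normal)) "normal" else "abnormal"
}

#' Derive the longitudinal diagnosis class from a visit sequence
#'
#' Collapses a subject's chronologically ordered per-visit diagnoses
#' (`NL`, `MCI`, `Dementia`) into the time-invariant class:
#' \describe{
#'   \item{sHC}{normal at every visit}
#'   \item{cMCI}{started normal, reached MCI, never Dementia}
#'   \item{sMCI}{started MCI, never Dementia}
#'   \item{cAD}{reached Dementia after starting NL or MCI}
#'   \item{sAD}{Dementia at every visit}
#' }
#' A reversion after Dementia (e.g. Dementia then NL) is inconsistent with a
#' progressive diagnosis; it triggers a warning but the sequence is still
#' classified by the presence-of-Dementia rule.
#'
#' @param dx_age Character vector of per-visit diagnoses in `{NL, MCI,
#'   Dementia}`, in chronological order.
#' @return One of `"sHC"`, `"sMCI"`, `"cMCI"`, `"sAD"`, `"cAD"`.
#' @examples
#' derive_dx_last(c("NL", "NL", "NL"))          # sHC
#' derive_dx_last(c("NL", "MCI", "Dementia"))   # cAD
#' @export
derive_dx_last <- function(dx_age) {
  if (length(dx_age) == 0) stop_config("empty diagnosis sequence")
  valid <- c("NL", "MCI", "Dementia")
  bad <- setdiff(unique(dx_age), valid)
  if (length(bad) > 0)
    stop_config("invalid diagnosis label(s): %s", paste(bad, collapse = ", "))
  if (any(dx_age == "Dementia")) {
    last_dem <- max(which(dx_age == "Dementia"))
    if (last_dem < length(dx_age))
      warning("diagnosis sequence reverts after Dementia; classified by the presence of Dementia",
              call. = FALSE)
    if (dx_age[1] == "Dementia") return("sAD") else return("cAD")
  }
  if (all(dx_age == "NL")) return("sHC")
  if (dx_age[1] == "NL") return("cMCI")
  "sMCI"
}

#' Combine longitudinal class and CSF profile into the dx_csf label
#'
#' The six `dx_csf` labels cross the coarse clinical class of `dx_last`
#' (HC / MCI / AD) with the CSF profile; an unknown profile yields
#' `"unknown"`.
#'
#' @param dx_last Longitudinal class (`sHC`, `sMCI`, `cMCI`, `sAD`, `cAD`).
#' @param csf_profile `"normal"`, `"abnormal"` or `"unknown"`.
#' @return A label such as `"normal-HCcsf"` or `"abnormal-ADcsf"`.
#' @export
derive_dx_csf <- function(dx_last, csf_profile) {
  if (!dx_last %in% c("sHC", "sMCI", "cMCI", "sAD", "cAD"))
    stop_config("invalid dx_last: %s", dx_last)
  if (!csf_profile %in% c("normal", "abnormal", "unknown"))
    stop_config("invalid csf_profile: %s", csf_profile)
  if (csf_profile == "unknown") return("unknown")
  sprintf("%s-%scsf", csf_profile, coarse_class(dx_last))
}

#' Label every subject of a cohort
#'
#' Orders each subject's visits chronologically, derives `dx_last`, the CSF
#' profile (over all available CSF observations) and `dx_csf`.
#'
#' @param cohort Cohort data frame (see [read_cohort()] for the schema).
#' @param abeta_cutoff,tau_cutoff CSF cut-offs in pg/mL.
#' @return Data frame with one row per subject: `subject_id`, `gender`,
#'   `dx_last`, `csf_profile`, `dx_csf`.
#' @export
label_subjects <- function(cohort, abeta_cutoff = 192, tau_cutoff = 93) {
  ids <- unique(cohort$subject_id)
  out <- lapply(ids, function(sid) {
    rows <- cohort[cohort$subject_id == sid, , drop = FALSE]
    rows <- rows[order(rows$visit_month), , drop = FALSE]
    dx_last <- derive_dx_last(rows$dx_age)
    prof <- classify_csf_profile(rows$csf_abeta, rows$csf_tau,
                                 abeta_cutoff, tau_cutoff)
    data.frame(subject_id = sid, gender = rows$gender[1], dx_last = dx_last,
               csf_profile = prof, dx_csf = derive_dx_csf(dx_last, prof),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split a cohort into the null-model and early-prediction cohorts
#'
#' The null-model cohort holds the stable healthy controls with a normal CSF
#' profile (`dx_csf == "normal-HCcsf"`); every other subject goes to the
#' early-prediction cohort. The two parts are disjoint and exhaustive.
#'
#' @param cohort Cohort data frame.
#' @param labels Per-subject labels from [label_subjects()].
#' @return List with elements `null_cohort` and `early_cohort` (data frames).
#' @export
split_cohorts <- function(cohort, labels) {
  missing <- setdiff(unique(cohort$subject_id), labels$subject_id)
  if (length(missing) > 0)
    stop_config("labels missing for %d subject(s), e.g. %s",
                length(missing), missing[1])
  null_ids <- labels$subject_id[labels$dx_csf == "normal-HCcsf"]
  if (length(null_ids) == 0)
    stop("cannot build a null model: no normal-HCcsf subjects in the cohort",
         call. = FALSE)
  list(
    null_cohort = cohort[cohort$subject_id %in% null_ids, , drop = FALSE],
    early_cohort = cohort[!cohort$subject_id %in% null_ids, , drop = FALSE]
  )
}
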