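#' Predict age-expected biomarker values for each observation
#'
#' For subject `i`, visit `j`, ROI `r` the expected value under the null
#' (healthy-aging) model is
#' \deqn{\hat y_{ijr} = y0_{ir} + \beta_a^r \, age_{ij} + \beta_e^r \, educ_i,}
#' i.e. the subject's baseline intercept carried along the null-cohort fixed
#' effects. At age 0 the expected value equals `y0` by construction.
#'
#' @param y0 Subjects x ROIs intercept matrix (variant intercepts inferred by
#'   [infer_vr_intercepts()], quasi-variant from
#'   [estimate_qvr_intercepts()]).
#' @param cohort Standardized cohort data frame providing `subject_id`,
#'   `age_years`, `educ_years` per observation.
#' @param fits Named list of null-model [fit_lme()] results for the ROIs of
#'   `y0`.
#' @return Matrix, observations x ROIs, of expected values (`NA` where the
#'   subject's `y0` is missing).
#' @export
predict_expected <- function(y0, cohort, fits) {
  rois <- colnames(y0)
  missing_fits <- setdiff(rois, names(fits))
  if (length(missing_fits) > 0)
    stop_config("no null-model fit for ROI(s): %s",
                paste(missing_fits, collapse = ", "))
  unknown <- setdiff(unique(cohort$subject_id), rownames(y0))
  if (length(unknown) > 0)
    stop_config("y0 missing for subject(s): %s",
                paste(utils::head(unknown, 3), collapse = ", "))
  idx <- match(cohort$subject_id, rownames(y0))
  out <- matrix(NA_real_, nrow(cohort), length(rois),
                dimnames = list(NULL, rois))
  for (r in rois) {
    f <- fits[[r]]
    out[, r] <- y0[idx, r] + f$beta[["age"]] * cohort$age_years +
      f$beta[["educ"]] * cohort$educ_years
  }
  out
}

#' Compute the residual matrix E
#'
#' Elementwise deviation of the observed from the age-expected value,
#' `e_ijr = y_ijr - yhat_ijr`: the normative deviation score used as the
#' classification feature. Missing observed or expected cells give missing
#' residuals.
#'
#' @param observed Observations x ROIs matrix of observed (standardized)
#'   values.
#' @param expected Matching matrix from [predict_expected()].
#' @param meta Optional data frame of per-observation metadata
#'   (`subject_id`, `visit_month`, ...) carried as attribute `meta`.
#' @return Object of class `residual_matrix` (numeric matrix with `meta`
#'   attribute).
#' @export
compute_residuals <- function(observed, expected, meta = NULL) {
  observed <- as.matrix(observed)
  if (!identical(dim(observed), dim(expected)))
    stop_config("observed (%d x %d) and expected (%d x %d) shapes differ",
                nrow(observed), ncol(observed), nrow(expected), ncol(expected))
  if (!is.null(colnames(observed)) && !is.null(colnames(expected)) &&
      !identical(colnames(observed), colnames(expected)))
    stop_config("observed and expected ROI columns differ")
  e <- observed - expected
  if (!is.null(meta) && nrow(meta) != nrow(e))
    stop_config("meta has %d rows but residuals have %d", nrow(meta), nrow(e))
  attr(e, "meta") <- meta
  class(e) <- c("residual_matrix", class(e))
  e
}

#' Select the retained residual columns (E_v)
#'
#' Keeps every variant-ROI column, and every quasi-variant column whose
#' residuals are not identically zero (tolerance 1e-12) across all
#' observations; excluded-ROI columns are dropped. Quasi-variant residual
#' columns are identically zero exactly for subjects observed once under the
#' mean-of-adjusted-observations intercept rule, so this filter removes only
#' columns that carry no signal, which provably leaves any downstream
#' classifier unchanged.
#'
#' @param E [compute_residuals()] output.
#' @param classification [classify_rois()] output with `roi` and `label`.
#' @return The residual matrix restricted to the retained columns (metadata
#'   preserved).
#' @export
build_Ev <- function(E, classification) {
  labs <- stats::setNames(classification$label, classification$roi)
  rois <- colnames(E)
  keep <- vapply(rois, function(r) {
    lab <- labs[[r]] %||% "excluded"
    if (lab == "vr") return(TRUE)
    if (lab != "qvr") return(FALSE)
    any(abs(E[, r]) > 1e-12, na.rm = TRUE)
  }, logical(1))
  out <- E[, keep, drop = FALSE]
  attr(out, "meta") <- attr(E, "meta")
  class(out) <- class(E)
  out
}

#' Assemble a classification feature set from residuals
#'
#' Builds the per-observation design matrix: the retained residual columns
#' plus age (`F1`), optionally plus the MMSE and CDR global scores (`F2`).
#' Labels are the coarse clinical class (HC/MCI/AD) of either the diagnosis
#' at the visit (`label_mode = "current"`, subject classification) or of the
#' subject's last known longitudinal class (`label_mode = "last"`, early
#' prediction: every row of a converter is labelled with the future outcome).
#'
#' @param Ev Retained residual matrix from [build_Ev()]; its `meta` attribute
#'   must carry `subject_id`, `gender`, `visit_month`, `age_years`, `dx_age`,
#'   `dx_last`, `mmse`, `cdr_global`.
#' @param variant `"F1"` or `"F2"`.
#' @param label_mode `"current"` or `"last"`.
#' @return Object of class `feature_set`: list with `x` (design matrix),
#'   `label` (factor HC/MCI/AD), `meta` (per-row metadata), `variant`,
#'   `label_mode`.
#' @export
assemble_features <- function(Ev, variant = c("F1", "F2"),
                              label_mode = c("current", "last")) {
  variant <- match.arg(variant)
  label_mode <- match.arg(label_mode)
  meta <- attr(Ev, "meta")
  if (is.null(meta))
    stop_config("Ev carries no metadata; build it via compute_residuals(meta=)")
  x <- cbind(unclass(Ev), age = meta$age_years)
  if (variant == "F2")
    x <- cbind(x, mmse = meta$mmse, cdr_global = meta$cdr_global)
  label <- if (label_mode == "current") coarse_class(meta$dx_age)
           else coarse_class(meta$dx_last)
  keep <- stats::complete.cases(x) & !is.na(label)
  if (sum(!keep) > 0)
    message(sprintf("assemble_features: dropping %d row(s) with missing features or labels",
                    sum(!keep)))
  out <- list(x = x[keep, , drop = FALSE],
              label = factor(label[keep], levels = c("HC", "MCI", "AD")),
              meta = meta[keep, , drop = FALSE],
              variant = variant, label_mode = label_mode)
  class(out) <- "feature_set"
  out
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set %s/%s> %d observations x %d features; labels: %s\n",
              x$variant, x$label_mode, nrow(x$x), ncol(x$x),
              paste(sprintf("%s=%d", levels(x$label), table(x$label)),
                    collapse = " ")))
  invisible(x)
}
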