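#' Estimate per-ROI standardization parameters on the null cohort
#'
#' Computes, for every `roi_*` column, the mean and (sample) standard
#' deviation over all pooled null-cohort observations. ROIs with zero
#' variance are dropped with a warning. Applying the parameters to the null
#' cohort itself yields pooled mean 0 and SD 1 per retained ROI; new cohorts
#' are standardized with the *same* null-cohort parameters.
#'
#' @param cohort Null-cohort data frame.
#' @return Object of class `standardization_params`: data frame with columns
#'   `roi`, `center`, `scale`, plus attribute `dropped` (zero-variance ROIs).
#' @export
fit_standardization <- function(cohort) {
  rois <- roi_columns(cohort)
  if (length(rois) == 0 || nrow(cohort) == 0)
    stop_config("null cohort is empty or has no roi_* columns")
  m <- vapply(rois, function(r) mean(cohort[[r]], na.rm = TRUE), numeric(1))
  s <- vapply(rois, function(r) stats::sd(cohort[[r]], na.rm = TRUE), numeric(1))
  constant <- !is.finite(s) | s < 1e-12
  if (any(constant)) {
    warning(sprintf("dropping %d constant ROI(s): %s", sum(constant),
                    paste(rois[constant], collapse = ", ")), call. = FALSE)
  }
  params <- data.frame(roi = rois[!constant], center = m[!constant],
                       scale = s[!constant], stringsAsFactors = FALSE)
  rownames(params) <- NULL
  attr(params, "dropped") <- rois[constant]
  class(params) <- c("standardization_params", "data.frame")
  params
}

#' Standardize a cohort with previously fitted parameters
#'
#' @param cohort Cohort data frame.
#' @param params [fit_standardization()] output (from the null cohort).
#' @return The cohort with retained ROI columns centred and scaled; ROI
#'   columns absent from `params` (dropped as constant) are removed.
#' @export
apply_standardization <- function(cohort, params) {
  keep <- intersect(roi_columns(cohort), params$roi)
  missing <- setdiff(params$roi, roi_columns(cohort))
  if (length(missing) > 0)
    stop_schema("cohort lacks ROI column(s) required by the standardization: %s",
                paste(missing, collapse = ", "))
  drop <- setdiff(roi_columns(cohort), keep)
  out <- cohort[, setdiff(names(cohort), drop), drop = FALSE]
  idx <- match(keep, params$roi)
  for (i in seq_along(keep))
    out[[keep[i]]] <- (out[[keep[i]]] - params$center[idx[i]]) / params$scale[idx[i]]
  out
}
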