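#' Fit the complete normative null model on a null cohort
#'
#' Runs the full null-model stage on the stable healthy controls with a
#' normal CSF profile: per-ROI standardization (zero mean, unit variance on
#' the pooled null observations), one random-intercept mixed model per ROI,
#' variant/quasi-variant classification of the ROIs by annual standardized
#' change, extraction of the subjects-by-ROI baseline intercept table, and
#' the kernel-PLSR transfer model that infers variant intercepts from
#' quasi-variant intercepts.
#'
#' @param null_cohort Null-cohort data frame (raw scale).
#' @param threshold Annual-change threshold in SD units/year (default 0.01,
#'   i.e. 1% of the ROI's SD per year).
#' @param alpha Significance level for the age effect.
#' @param max_components Maximum PLSR components considered by LOO.
#' @return Object of class `null_model`: list with `standardization`, `fits`,
#'   `classification`, `intercepts` (subjects x ROIs), `vr_rois`, `qvr_rois`,
#'   `plsr`, `n_subjects`.
#' @export
fit_null_model <- function(null_cohort, threshold = 0.01, alpha = 0.05,
                           max_components = 10) {
  std <- fit_standardization(null_cohort)
  cohort_std <- apply_standardization(null_cohort, std)
  fits <- fit_null_lmes(cohort_std)
  cls <- classify_rois(fits, threshold = threshold, alpha = alpha)
  vr <- cls$roi[cls$label == "vr"]
  qvr <- cls$roi[cls$label == "qvr"]
  if (length(vr) == 0 || length(qvr) == 0)
    stop_config("null model needs both variant (%d) and quasi-variant (%d) ROIs",
                length(vr), length(qvr))
  y0 <- extract_intercepts(fits)
  plsr <- fit_plsr(y0[, qvr, drop = FALSE], y0[, vr, drop = FALSE],
                   max_components = max_components)
  out <- list(standardization = std, fits = fits, classification = cls,
              intercepts = y0, vr_rois = vr, qvr_rois = qvr, plsr = plsr,
              threshold = threshold, alpha = alpha,
              n_subjects = length(unique(null_cohort$subject_id)))
  class(out) <- "null_model"
  out
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("<null_model> %d subjects; %d vr + %d qvr ROIs (threshold %.3g SD/yr, alpha %.2f); PLSR %d component(s)\n",
              x$n_subjects, length(x$vr_rois), length(x$qvr_rois),
              x$threshold, x$alpha, x$plsr$ncomp))
  invisible(x)
}

#' Write / read a null-model bundle
#'
#' Serializes a fitted [fit_null_model()] into a directory of plain-text
#' artifacts: `standardization.csv`, `roi_fits.csv` (fixed effects, variance
#' components, Wald p-values and vr/qvr labels), `intercepts.csv`, the PLSR
#' weight/loading matrices (`plsr_*.csv`) and `meta.yaml`. `read_null_bundle()`
#' reconstructs an equivalent model (PLSR coefficients are rebuilt from the
#' stored weights and loadings).
#'
#' @param model A `null_model` object.
#' @param dir Bundle directory (created if absent).
#' @return `write_null_bundle()` returns `dir` invisibly; `read_null_bundle()`
#'   returns a `null_model` object.
#' @export
write_null_bundle <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(model$standardization),
                   file.path(dir, "standardization.csv"), row.names = FALSE)
  fits_df <- do.call(rbind, lapply(model$fits, function(f) data.frame(
    roi = f$roi, beta_intercept = f$beta[["intercept"]],
    beta_age = f$beta[["age"]], beta_educ = f$beta[["educ"]],
    se_age = f$se_age, p_age = f$p_age, psi = f$psi, sigma2 = f$sigma2,
    n_subjects = f$n_subjects, n_obs = f$n_obs,
    converged = f$converged, singular = isTRUE(f$singular),
    degenerate = isTRUE(f$degenerate), stringsAsFactors = FALSE)))
  fits_df$label <- model$classification$label[
    match(fits_df$roi, model$classification$roi)]
  utils::write.csv(fits_df, file.path(dir, "roi_fits.csv"), row.names = FALSE)
  ic <- data.frame(subject_id = rownames(model$intercepts),
                   model$intercepts, check.names = FALSE)
  utils::write.csv(ic, file.path(dir, "intercepts.csv"), row.names = FALSE)
  p <- model$plsr
  utils::write.csv(data.frame(p$W), file.path(dir, "plsr_W.csv"), row.names = FALSE)
  utils::write.csv(data.frame(p$P), file.path(dir, "plsr_P.csv"), row.names = FALSE)
  utils::write.csv(data.frame(p$Q), file.path(dir, "plsr_Q.csv"), row.names = FALSE)
  centers <- data.frame(role = c(rep("predictor", length(p$xmeans)),
                                 rep("response", length(p$ymeans))),
                        roi = c(p$predictors, p$responses),
                        center = c(unname(p$xmeans), unname(p$ymeans)),
                        stringsAsFactors = FALSE)
  utils::write.csv(centers, file.path(dir, "plsr_centers.csv"), row.names = FALSE)
  yaml::write_yaml(list(
    threshold = model$threshold, alpha = model$alpha,
    n_subjects = model$n_subjects,
    vr_rois = model$vr_rois, qvr_rois = model$qvr_rois,
    plsr = list(ncomp = p$ncomp, max_rank = p$max_rank,
                rmsep = as.numeric(p$rmsep), rmsep0 = p$rmsep0,
                n_subjects = p$n_subjects)),
    file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_null_bundle
#' @export
read_null_bundle <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  std <- utils::read.csv(file.path(dir, "standardization.csv"),
                         stringsAsFactors = FALSE)
  class(std) <- c("standardization_params", "data.frame")
  fits_df <- utils::read.csv(file.path(dir, "roi_fits.csv"),
                             stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(fits_df)), function(i) {
    r <- fits_df[i, ]
    structure(list(roi = r$roi,
                   beta = c(intercept = r$beta_intercept, age = r$beta_age,
                            educ = r$beta_educ),
                   se_age = r$se_age, p_age = r$p_age, psi = r$psi,
                   sigma2 = r$sigma2, y0 = NULL, n_subjects = r$n_subjects,
                   n_obs = r$n_obs, converged = r$converged,
                   singular = r$singular, degenerate = r$degenerate),
              class = "lme_fit")
  })
  names(fits) <- fits_df$roi
  cls <- fits_df[, c("roi", "beta_age", "p_age", "label")]
  ic <- utils::read.csv(file.path(dir, "intercepts.csv"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  intercepts <- as.matrix(ic[, -1, drop = FALSE])
  dimnames(intercepts) <- list(ic$subject_id, as.character(names(ic)[-1]))
  W <- unname(as.matrix(utils::read.csv(file.path(dir, "plsr_W.csv"))))
  P <- unname(as.matrix(utils::read.csv(file.path(dir, "plsr_P.csv"))))
  Q <- unname(as.matrix(utils::read.csv(file.path(dir, "plsr_Q.csv"))))
  centers <- utils::read.csv(file.path(dir, "plsr_centers.csv"),
                             stringsAsFactors = FALSE)
  xm <- centers[centers$role == "predictor", ]
  ym <- centers[centers$role == "response", ]
  B <- lapply(seq_len(ncol(W)), function(a) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    Qa <- Q[, seq_len(a), drop = FALSE]
    Wa %*% solve(crossprod(Pa, Wa), t(Qa))
  })
  plsr <- structure(list(
    predictors = xm$roi, responses = ym$roi,
    xmeans = stats::setNames(xm$center, xm$roi),
    ymeans = stats::setNames(ym$center, ym$roi),
    W = W, P = P, Q = Q, B = B, max_rank = meta$plsr$max_rank,
    ncomp = meta$plsr$ncomp, rmsep = meta$plsr$rmsep,
    rmsep0 = meta$plsr$rmsep0, n_subjects = meta$plsr$n_subjects),
    class = "plsr_model")
  structure(list(standardization = std, fits = fits, classification = cls,
                 intercepts = intercepts, vr_rois = meta$vr_rois,
                 qvr_rois = meta$qvr_rois, plsr = plsr,
                 threshold = meta$threshold, alpha = meta$alpha,
                 n_subjects = meta$n_subjects),
            class = "null_model")
}

#' Compute the residual matrix of a cohort under a fitted null model
#'
#' Standardizes the cohort with the null-cohort parameters, estimates each
#' subject's quasi-variant intercepts from their adjusted observations,
#' infers the variant intercepts through the PLSR transfer model, predicts
#' the age-expected value of every retained ROI at every visit, and returns
#' the observed-minus-expected residual matrix with per-observation metadata
#' (including `dx_last` merged from `labels`).
#'
#' @param cohort Cohort data frame (raw scale; the early-prediction cohort).
#' @param model A [fit_null_model()] result.
#' @param labels Per-subject labels from [label_subjects()].
#' @return A `residual_matrix` (see [compute_residuals()]) restricted to the
#'   retained columns (see [build_Ev()]).
#' @export
cohort_residuals <- function(cohort, model, labels) {
  cohort_std <- apply_standardization(cohort, model$standardization)
  rois <- c(model$vr_rois, model$qvr_rois)
  qvr_y0 <- estimate_qvr_intercepts(cohort_std, model$fits, model$qvr_rois)
  vr_y0 <- infer_vr_intercepts(model$plsr, qvr_y0)
  y0 <- cbind(vr_y0, qvr_y0)[, rois, drop = FALSE]
  expected <- predict_expected(y0, cohort_std, model$fits)
  observed <- as.matrix(cohort_std[, rois, drop = FALSE])
  meta <- cohort_std[, intersect(c("subject_id", "gender", "visit_month",
                                   "age_years", "educ_years", "dx_age",
                                   "mmse", "cdr_global"), names(cohort_std))]
  meta$dx_last <- labels$dx_last[match(meta$subject_id, labels$subject_id)]
  E <- compute_residuals(observed, expected, meta = meta)
  build_Ev(E, model$classification)
}
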