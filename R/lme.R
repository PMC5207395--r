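#' Fit a random-intercept mixed model to one ROI's longitudinal values
#'
#' Fits, by REML via \pkg{lme4},
#' \deqn{y_{ij} = \beta_1 + \beta_a \, age_{ij} + \beta_e \, educ_i + v_i
#'       + \epsilon_{ij}, \quad v_i \sim N(0, \psi), \;
#'       \epsilon_{ij} \sim N(0, \sigma^2)}
#' with age in raw years (no centering), so the model intercept is literally
#' the extrapolation to age 0 and the subject-specific baseline value is
#' `y0_i = beta_1 + v_i` (fixed intercept plus the conditional mode of the
#' random effect). The p-value for the age effect is a two-sided Wald z-test
#' (estimate / SE against the standard normal). Unbalanced visit counts and
#' missing visits are handled naturally by the likelihood.
#'
#' If education is constant across subjects it is dropped from the fixed
#' effects (`beta_e = 0`). If the pooled data are exactly collinear (zero
#' residual variance, e.g. noise-free synthetic input) the model degenerates;
#' the fit then falls back to exact least squares with per-subject intercept
#' offsets and is flagged `degenerate`.
#'
#' @param y Numeric response vector (one ROI, typically standardized).
#' @param age Age at observation, years.
#' @param educ Years of education (constant within subject).
#' @param subject Subject identifier vector.
#' @param roi Optional ROI name carried in the result.
#' @return Object of class `lme_fit`: list with `roi`, `beta` (named
#'   `intercept`, `age`, `educ`), `se_age`, `p_age`, `psi`, `sigma2`, `y0`
#'   (named per-subject intercepts), `n_subjects`, `n_obs`, `converged`,
#'   `singular`, `degenerate`.
#' @export
fit_lme <- function(y, age, educ, subject, roi = NA_character_) {
  ok <- stats::complete.cases(y, age, educ, subject)
  d <- data.frame(y = y[ok], age = age[ok], educ = educ[ok],
                  subject = as.character(subject[ok]),
                  stringsAsFactors = FALSE)
  n_subj <- length(unique(d$subject))
  if (n_subj < 2)
    stop_config("fit_lme requires at least 2 subjects (got %d)", n_subj)
  if (length(unique(d$age)) < 2)
    stop_config("fit_lme requires at least 2 distinct ages")
  if (!any(table(d$subject) >= 2))
    stop_config("fit_lme requires repeated observations for at least one subject")

  use_educ <- stats::sd(d$educ) > 1e-12

  ## Degenerate (noise-free) input: once per-subject intercepts are allowed
  ## the residual variance is exactly zero and the profiled REML criterion is
  ## ill-defined, so solve the saturated least-squares problem directly. The
  ## education effect is collinear with the subject intercepts within the
  ## saturated fit; as in the REML limit, it is identified by the
  ## between-subject regression of raw intercepts on education.
  ols <- stats::lm(y ~ age + factor(subject), data = d)
  if (stats::var(stats::resid(ols)) < 1e-18 && !anyNA(stats::coef(ols))) {
    co <- stats::coef(ols)
    beta_a <- co[["age"]]
    subj_lev <- levels(factor(d$subject))
    offs <- c(0, co[grep("^factor\\(subject\\)", names(co))])
    y0_raw <- stats::setNames(co[["(Intercept)"]] + offs, subj_lev)
    educ_subj <- vapply(split(d$educ, d$subject), function(e) e[1], numeric(1))
    beta_e <- if (use_educ && stats::sd(educ_subj[subj_lev]) > 1e-12)
      stats::coef(stats::lm(y0_raw ~ educ_subj[subj_lev]))[[2]] else 0
    y0_subj <- y0_raw - beta_e * educ_subj[subj_lev]
    beta1 <- mean(y0_subj)
    fit <- list(roi = roi,
                beta = c(intercept = beta1, age = beta_a, educ = beta_e),
                se_age = 0, p_age = 0,
                psi = stats::var(y0_subj) * (length(y0_subj) - 1) / length(y0_subj),
                sigma2 = 0,
                y0 = y0_subj, n_subjects = n_subj, n_obs = nrow(d),
                converged = TRUE, singular = FALSE, degenerate = TRUE)
    class(fit) <- "lme_fit"
    return(fit)
  }

  form <- if (use_educ) y ~ age + educ + (1 | subject) else y ~ age + (1 | subject)
  converged <- TRUE
  mod <- withCallingHandlers(
    tryCatch(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      error = function(e) e),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  if (inherits(mod, "error"))
    return(structure(list(roi = roi, beta = c(intercept = NA, age = NA, educ = NA),
                          se_age = NA, p_age = NA, psi = NA, sigma2 = NA,
                          y0 = NULL, n_subjects = n_subj, n_obs = nrow(d),
                          converged = FALSE, singular = NA, degenerate = FALSE),
                     class = "lme_fit"))

  fe <- lme4::fixef(mod)
  vc <- as.data.frame(lme4::VarCorr(mod))
  psi <- vc$vcov[vc$grp == "subject"]
  sigma2 <- stats::sigma(mod)^2
  se_age <- sqrt(diag(as.matrix(stats::vcov(mod)))[["age"]])
  z <- fe[["age"]] / se_age
  re <- lme4::ranef(mod)$subject
  y0 <- fe[["(Intercept)"]] + re[["(Intercept)"]]
  names(y0) <- rownames(re)

  fit <- list(
    roi = roi,
    beta = c(intercept = fe[["(Intercept)"]], age = fe[["age"]],
             educ = if (use_educ) fe[["educ"]] else 0),
    se_age = se_age,
    p_age = 2 * stats::pnorm(-abs(z)),
    psi = psi, sigma2 = sigma2, y0 = y0,
    n_subjects = n_subj, n_obs = nrow(d),
    converged = converged, singular = lme4::isSingular(mod),
    degenerate = FALSE)
  class(fit) <- "lme_fit"
  fit
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("<lme_fit %s> beta_age=%.4f (SE %.4f, p=%.3g) psi=%.4f sigma2=%.4f [%d subj, %d obs]%s\n",
              x$roi %||% "?", x$beta[["age"]], x$se_age, x$p_age, x$psi,
              x$sigma2, x$n_subjects, x$n_obs,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Fit the per-ROI null mixed models for a (standardized) null cohort
#'
#' Fits [fit_lme()] to every `roi_*` column observed at two or more distinct
#' time points; ROIs failing that inclusion rule or failing to converge are
#' reported but excluded from downstream classification.
#'
#' @param cohort Standardized null-cohort data frame.
#' @return Named list of `lme_fit` objects (one per fitted ROI).
#' @export
fit_null_lmes <- function(cohort) {
  rois <- roi_columns(cohort)
  if (length(rois) == 0) stop_config("no roi_* columns to fit")
  fits <- list()
  for (r in rois) {
    if (length(unique(cohort$visit_month[!is.na(cohort[[r]])])) < 2) {
      warning(sprintf("ROI %s observed at fewer than 2 time points; skipped", r),
              call. = FALSE)
      next
    }
    fits[[r]] <- fit_lme(cohort[[r]], cohort$age_years, cohort$educ_years,
                         cohort$subject_id, roi = r)
  }
  fits
}

#' Classify ROIs as variant, quasi-variant or excluded
#'
#' A ROI is *variant* (`vr`) when its annual standardized change exceeds the
#' threshold in magnitude AND the age effect is significant; *quasi-variant*
#' (`qvr`) when the magnitude is at or below the threshold. The remaining
#' combination (large but non-significant change) fits neither definition and
#' is labelled `excluded`, as are non-converged fits. Because ROIs are
#' standardized to unit variance, the default threshold 0.01 corresponds to
#' an annual change of 1% of the ROI's standard deviation.
#'
#' @param fits List of [fit_lme()] results.
#' @param threshold Annual-change threshold in SD units/year.
#' @param alpha Significance level for the age effect.
#' @return Data frame: `roi`, `beta_age`, `p_age`, `label`.
#' @export
classify_rois <- function(fits, threshold = 0.01, alpha = 0.05) {
  if (threshold <= 0 || alpha <= 0 || alpha >= 1)
    stop_config("threshold must be > 0 and alpha in (0, 1)")
  rows <- lapply(fits, function(f) {
    label <- if (!isTRUE(f$converged) || is.na(f$beta[["age"]])) "excluded"
    else if (abs(f$beta[["age"]]) > threshold && f$p_age <= alpha) "vr"
    else if (abs(f$beta[["age"]]) <= threshold) "qvr"
    else "excluded"
    data.frame(roi = f$roi, beta_age = f$beta[["age"]], p_age = f$p_age,
               label = label, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Extract the subjects-by-ROI baseline intercept table
#'
#' Collects `y0_ir = beta_1^r + v_ir` (fixed intercept plus conditional
#' random-effect mode) from each fit into a matrix with one row per
#' null-cohort subject and one column per ROI; subjects absent from a fit get
#' `NA`.
#'
#' @param fits Named list of [fit_lme()] results.
#' @return Numeric matrix, subjects x ROIs.
#' @export
extract_intercepts <- function(fits) {
  fits <- Filter(function(f) !is.null(f$y0), fits)
  if (length(fits) == 0) stop_config("no converged fits to extract intercepts from")
  subjects <- sort(unique(unlist(lapply(fits, function(f) names(f$y0)))))
  out <- matrix(NA_real_, length(subjects), length(fits),
                dimnames = list(subjects,
                                unname(vapply(fits, function(f) f$roi, ""))))
  for (j in seq_along(fits))
    out[names(fits[[j]]$y0), j] <- fits[[j]]$y0
  out
}
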