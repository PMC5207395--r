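#' Generate a synthetic ADNI-like longitudinal cohort with known ground truth
#'
#' Simulates subject-visit biomarker data under the same generative structure
#' the normative pipeline assumes: for subject `i`, visit `j` and ROI `r`,
#'
#' \deqn{y_{ijr} = y0_{ir} + \beta_a^r \cdot age_{ij} + \beta_e^r \cdot educ_i
#'       - d_{ijr} + \epsilon_{ijr}}
#'
#' where subject intercepts are built from shared latent factors,
#' `y0_i = L f_i + noise`, so a linear map from quasi-variant to variant
#' intercepts exists by construction, and `d_ijr` is the disease effect on
#' affected ROIs (an offset scaled by the biomarker state, NL = 0, MCI = 1/2,
#' Dementia = 1, plus an extra atrophy slope accruing from Dementia-state
#' onset). Converters (`cMCI`, `cAD`) change clinical state at a conversion
#' visit drawn uniformly from their realized non-baseline visits; the
#' biomarker state may lead the clinical state by
#' `config$biomarker_lead_visits` visits. CSF amyloid/tau are drawn at
#' baseline from group-specific mixtures; MMSE and the CDR global score track
#' the clinical state at each visit. Dropout is monotone: once a subject
#' misses a visit, all later visits are missing.
#'
#' @param config A [generator_config()] object.
#' @return A list with components:
#'   \describe{
#'     \item{cohort}{Long-format data frame, one row per subject-visit:
#'       `subject_id`, `gender`, `visit_month`, `age_years`, `educ_years`,
#'       `dx_bl`, `dx_age`, `mmse`, `cdr_global`, `csf_abeta`, `csf_tau`
#'       (CSF only at baseline), then one `roi_*` column per biomarker.}
#'     \item{truth}{Ground-truth list: per-ROI slopes/education effects and
#'       vr/qvr labels, the loading matrix `L`, per-subject intercept matrix
#'       `y0`, latent factors, the implied qvr-to-vr linear map, affected-ROI
#'       names, per-subject conversion month, and (if destandardized) the
#'       per-ROI affine constants.}
#'   }
#' @examples
#' cfg <- generator_config(n_subjects_per_group = c(sHC = 5, sMCI = 2,
#'   cMCI = 2, sAD = 2, cAD = 2), n_vr_rois = 4, n_qvr_rois = 4, seed = 7)
#' sim <- generate_cohort(cfg)
#' head(sim$cohort[, 1:8])
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    stop_config("config must be created with generator_config()")
  validate_generator_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

#' @noRd
generate_cohort_impl <- function(cfg) {
  n_vr <- cfg$n_vr_rois
  n_qvr <- cfg$n_qvr_rois
  n_roi <- n_vr + n_qvr
  roi_names <- c(if (n_vr > 0) sprintf("roi_vr%03d", seq_len(n_vr)),
                 if (n_qvr > 0) sprintf("roi_qvr%03d", seq_len(n_qvr)))
  roi_type <- c(rep("vr", n_vr), rep("qvr", n_qvr))

  ## Per-ROI fixed effects (SD units / year)
  slopes <- numeric(n_roi)
  if (n_vr > 0) {
    mag <- stats::runif(n_vr, cfg$slope_vr_range[1], cfg$slope_vr_range[2])
    sgn <- ifelse(stats::runif(n_vr) < cfg$vr_negative_prob, -1, 1)
    slopes[seq_len(n_vr)] <- sgn * mag
  }
  if (n_qvr > 0)
    slopes[n_vr + seq_len(n_qvr)] <-
      stats::runif(n_qvr, -cfg$slope_qvr_max, cfg$slope_qvr_max)
  educ_eff <- stats::runif(n_roi, cfg$educ_effect_range[1], cfg$educ_effect_range[2])

  ## Latent intercept structure shared across ROI sets
  L <- matrix(stats::rnorm(n_roi * cfg$latent_dim,
                           sd = cfg$intercept_sd / sqrt(cfg$latent_dim)),
              nrow = n_roi, ncol = cfg$latent_dim,
              dimnames = list(roi_names, NULL))

  ## Disease-affected ROIs: a subset of the variant set only, so quasi-variant
  ## regions stay disease-free (the identification assumption of the method).
  n_affected <- round(cfg$affected_fraction * n_vr)
  affected <- if (n_affected > 0) sort(sample(seq_len(n_vr), n_affected)) else integer(0)
  affected_names <- roi_names[affected]

  groups <- c("sHC", "sMCI", "cMCI", "sAD", "cAD")
  severity <- c(NL = 0, MCI = 0.5, Dementia = 1)
  dx_bl_of <- c(sHC = "CN", sMCI = "LMCI", cMCI = "CN", sAD = "AD", cAD = "LMCI")

  rows <- list()
  subj_meta <- list()
  y0_all <- list()
  f_all <- list()
  k <- 0L
  for (gender in c("F", "M")) {
    for (grp in groups) {
      n_g <- cfg$n_subjects_per_group[[grp]]
      if (n_g == 0) next
      for (s in seq_len(n_g)) {
        k <- k + 1L
        sid <- sprintf("S%s_%s_%03d", gender, grp, s)
        age0 <- stats::runif(1, cfg$age_baseline_range[1], cfg$age_baseline_range[2])
        educ <- sample(seq(cfg$educ_years_range[1], cfg$educ_years_range[2]), 1)
        f_i <- stats::rnorm(cfg$latent_dim)
        y0_i <- drop(L %*% f_i) + stats::rnorm(n_roi, sd = cfg$intercept_noise_sd)

        ## Monotone dropout; converters need at least two realized visits so a
        ## non-baseline conversion visit exists.
        repeat {
          keep <- c(TRUE, cumprod(stats::runif(length(cfg$visit_months) - 1) >
                                    cfg$dropout_prob) > 0)
          if (sum(keep) >= 2 || !(grp %in% c("cMCI", "cAD"))) break
        }
        months <- cfg$visit_months[keep]
        n_v <- length(months)

        conv_idx <- NA_integer_
        if (grp %in% c("cMCI", "cAD"))
          conv_idx <- if (n_v == 2) 2L else sample(2:n_v, 1)

        clin_state <- switch(grp,
          sHC  = rep("NL", n_v),
          sMCI = rep("MCI", n_v),
          sAD  = rep("Dementia", n_v),
          cMCI = ifelse(seq_len(n_v) < conv_idx, "NL", "MCI"),
          cAD  = ifelse(seq_len(n_v) < conv_idx, "MCI", "Dementia"))
        bio_idx <- if (is.na(conv_idx)) NA_integer_ else
          max(1L, conv_idx - cfg$biomarker_lead_visits)
        bio_state <- switch(grp,
          sHC  = rep("NL", n_v),
          sMCI = rep("MCI", n_v),
          sAD  = rep("Dementia", n_v),
          cMCI = ifelse(seq_len(n_v) < bio_idx, "NL", "MCI"),
          cAD  = ifelse(seq_len(n_v) < bio_idx, "MCI", "Dementia"))

        ages <- age0 + months / 12
        dem_onset_age <- if (any(bio_state == "Dementia"))
          ages[which(bio_state == "Dementia")[1]] else NA_real_

        ## Biomarker block: base line + disease effect + observation noise
        base <- outer(ages, slopes) +
          matrix(y0_i + educ_eff * educ, n_v, n_roi, byrow = TRUE)
        dis <- matrix(0, n_v, n_roi)
        if (length(affected) > 0 && grp != "sHC") {
          sev <- severity[bio_state]
          accel <- ifelse(bio_state == "Dementia",
                          cfg$disease_slope_accel * (ages - dem_onset_age), 0)
          dis[, affected] <- matrix(sev * cfg$disease_offset + accel,
                                    n_v, length(affected))
        }
        y <- base - dis
        if (cfg$obs_noise_sd > 0)
          y <- y + matrix(stats::rnorm(n_v * n_roi, sd = cfg$obs_noise_sd), n_v, n_roi)
        colnames(y) <- roi_names

        ## CSF at baseline only (longitudinal CSF is typically unavailable)
        cp <- cfg$csf_params[[grp]]
        path <- stats::runif(1) < cp$prob_abnormal
        ab <- if (path) cp$abeta_abnormal else cp$abeta_normal
        ta <- if (path) cp$tau_abnormal else cp$tau_normal
        csf_abeta <- c(max(1, stats::rnorm(1, ab[1], ab[2])), rep(NA_real_, n_v - 1))
        csf_tau <- c(max(1, stats::rnorm(1, ta[1], ta[2])), rep(NA_real_, n_v - 1))

        mmse <- vapply(clin_state, function(st) switch(st,
          NL = sample(28:30, 1), MCI = sample(24:27, 1), sample(18:23, 1)),
          numeric(1))
        cdr <- unname(c(NL = 0, MCI = 0.5, Dementia = 1)[clin_state])

        rows[[k]] <- data.frame(
          subject_id = sid, gender = gender, visit_month = months,
          age_years = ages, educ_years = educ,
          dx_bl = dx_bl_of[[grp]], dx_age = clin_state,
          mmse = unname(mmse), cdr_global = cdr,
          csf_abeta = csf_abeta, csf_tau = csf_tau,
          stringsAsFactors = FALSE)
        rows[[k]] <- cbind(rows[[k]], as.data.frame(y))
        subj_meta[[k]] <- data.frame(
          subject_id = sid, gender = gender, group = grp,
          age_baseline = age0, educ_years = educ,
          conversion_month = if (is.na(conv_idx)) NA_integer_ else months[conv_idx],
          biomarker_onset_month = if (is.na(bio_idx)) NA_integer_ else months[bio_idx],
          csf_pathology = path, stringsAsFactors = FALSE)
        y0_all[[k]] <- y0_i
        f_all[[k]] <- f_i
      }
    }
  }

  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  subjects <- do.call(rbind, subj_meta)
  rownames(subjects) <- NULL
  y0 <- do.call(rbind, y0_all)
  dimnames(y0) <- list(subjects$subject_id, roi_names)
  f <- do.call(rbind, f_all)
  rownames(f) <- subjects$subject_id

  ## Implied linear qvr -> vr intercept map (exact when intercept noise = 0):
  ## y0_vr = L_vr pinv(L_qvr) y0_qvr.
  qvr_to_vr_map <- NULL
  if (n_vr > 0 && n_qvr >= cfg$latent_dim) {
    L_vr <- L[seq_len(n_vr), , drop = FALSE]
    L_qvr <- L[n_vr + seq_len(n_qvr), , drop = FALSE]
    qvr_to_vr_map <- L_vr %*% MASS::ginv(L_qvr)
    dimnames(qvr_to_vr_map) <- list(roi_names[seq_len(n_vr)],
                                    roi_names[n_vr + seq_len(n_qvr)])
  }

  destd <- NULL
  if (cfg$destandardize) {
    destd <- data.frame(roi = roi_names,
                        center = stats::runif(n_roi, 1000, 10000),
                        scale = stats::runif(n_roi, 100, 1000))
    for (j in seq_len(n_roi))
      cohort[[roi_names[j]]] <- destd$center[j] + destd$scale[j] * cohort[[roi_names[j]]]
  }

  truth <- list(
    roi = data.frame(roi = roi_names, type = roi_type, slope = slopes,
                     educ_effect = educ_eff,
                     affected = roi_names %in% affected_names,
                     stringsAsFactors = FALSE),
    L = L, y0 = y0, latent = f,
    qvr_to_vr_map = qvr_to_vr_map,
    affected_rois = affected_names,
    subjects = subjects,
    destandardize = destd,
    config = cfg)
  list(cohort = cohort, truth = truth)
}

#' Write / read a cohort table
#'
#' `write_cohort()` stores the subject-visit table as CSV (missing values as
#' empty cells) with an optional YAML sidecar holding the generator
#' configuration. `read_cohort()` reads it back, validating the schema; the
#' round trip is lossless up to numeric printing precision.
#'
#' @param cohort Cohort data frame as produced by [generate_cohort()].
#' @param path CSV file path.
#' @param config Optional [generator_config()] written to `<path>.yaml`.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the cohort data frame.
#' @export
write_cohort <- function(cohort, path, config = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$csf_params <- lapply(cfg$csf_params, function(x) lapply(x, as.numeric))
    yaml::write_yaml(cfg, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_parse("cohort file not found: %s", path)
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                        check.names = FALSE)
  required <- c("subject_id", "gender", "visit_month", "age_years",
                "educ_years", "dx_age", "mmse", "cdr_global",
                "csf_abeta", "csf_tau")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_schema("cohort file is missing mandatory column(s): %s",
                paste(missing, collapse = ", "))
  rois <- roi_columns(df)
  if (length(rois) == 0)
    stop_schema("cohort file has no biomarker (roi_*) columns")
  numeric_cols <- c("visit_month", "age_years", "educ_years", "mmse",
                    "cdr_global", "csf_abeta", "csf_tau", rois)
  for (col in numeric_cols) {
    if (is.numeric(df[[col]]) || is.logical(df[[col]])) {
      df[[col]] <- as.numeric(df[[col]])
      next
    }
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]))
    if (length(bad) > 0)
      stop_parse("non-numeric value '%s' in column '%s' at row %d",
                 df[[col]][bad[1]], col, bad[1])
    df[[col]] <- parsed
  }
  df
}
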