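#' Default CSF biomarker mixture parameters by longitudinal diagnosis group
#'
#' Each group draws a per-subject "CSF pathology" indicator with probability
#' `prob_abnormal`; conditional on it, amyloid-beta 1-42 and total tau
#' concentrations (pg/mL) are drawn from the normal or abnormal Gaussian
#' component. The healthy components are centred on the values typical of
#' amyloid-negative elderly controls (Abeta ~ 247 +/- 20, tau ~ 55 +/- 12
#' pg/mL), so stable controls predominantly satisfy the normal-profile rule
#' (Abeta >= 192 and tau <= 93); the abnormal components sit on the other side
#' of both cut-offs, which makes the marginal Abeta distribution bimodal in
#' the impaired groups.
#'
#' @return Named list (one entry per group in `sHC`, `sMCI`, `cMCI`, `sAD`,
#'   `cAD`) of lists with elements `prob_abnormal`, `abeta_normal`,
#'   `abeta_abnormal`, `tau_normal`, `tau_abnormal` (each `c(mean, sd)`).
#' @export
default_csf_params <- function() {
  comp <- function(p) list(
    prob_abnormal  = p,
    abeta_normal   = c(247, 20),
    abeta_abnormal = c(135, 20),
    tau_normal     = c(55, 12),
    tau_abnormal   = c(115, 25)
  )
  list(sHC = comp(0.08), sMCI = comp(0.65), cMCI = comp(0.50),
       sAD = comp(0.90), cAD = comp(0.85))
}

#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defines the study conditions the generator emulates: an ADNI-like visit
#' schedule with monotone dropout, a random-intercept + age/education
#' fixed-effect structure per regional biomarker (ROI), subject intercepts
#' shared across ROIs through latent factors (so a linear quasi-variant to
#' variant intercept map exists by construction), stable and converting
#' diagnosis trajectories, group-dependent CSF mixtures and cognitive scores,
#' and disease-accelerated atrophy in a subset of variant ROIs.
#'
#' Biomarkers are generated on the standardized (SD-unit) scale: true annual
#' slopes are in SD units per year, so the variant regime must stay above the
#' 1%/year threshold used downstream and the quasi-variant regime below it.
#'
#' @param n_subjects_per_group Named integer vector, subjects per longitudinal
#'   diagnosis group (`sHC`, `sMCI`, `cMCI`, `sAD`, `cAD`) *per gender*.
#' @param n_vr_rois,n_qvr_rois Number of truly variant / quasi-variant ROIs.
#' @param visit_months Ordered integer visit schedule in months, starting at 0.
#' @param dropout_prob Per-visit probability of (monotone) dropout, in `[0, 1)`.
#' @param slope_vr_range Interval for variant-ROI annual slope magnitude
#'   (SD units/year); its lower end must exceed 0.01 so ground-truth labels are
#'   unambiguous.
#' @param vr_negative_prob Probability a variant ROI shrinks with age
#'   (atrophy) rather than grows (e.g. ventricular expansion).
#' @param slope_qvr_max Upper bound for quasi-variant slope magnitude
#'   (must be <= 0.005 SD units/year).
#' @param educ_effect_range Interval for the per-ROI education effect
#'   (SD units per year of education).
#' @param latent_dim Number of shared latent intercept factors.
#' @param intercept_sd Total SD of the latent part of subject intercepts.
#' @param intercept_noise_sd SD of ROI-specific intercept noise.
#' @param obs_noise_sd SD of the observation-level error.
#' @param disease_offset Intercept shift (SD units) subtracted from affected
#'   ROIs in the Dementia biomarker state; the MCI state receives half of it.
#' @param disease_slope_accel Additional annual atrophy (SD units/year) in
#'   affected ROIs, accruing from Dementia biomarker-state onset.
#' @param affected_fraction Fraction of variant ROIs carrying disease effects.
#' @param biomarker_lead_visits Number of visits by which the biomarker state
#'   transition precedes the clinical diagnosis transition in converters
#'   (0 = biomarkers change at the conversion visit).
#' @param csf_params Group-wise CSF mixture parameters; see
#'   [default_csf_params()].
#' @param educ_years_range Integer range education is sampled from (years).
#' @param age_baseline_range Baseline age drawn uniformly from this interval
#'   (years); the default spans the five-year strata 60-89.
#' @param destandardize If `TRUE`, each ROI is mapped to a raw scale by a
#'   per-ROI affine transform (stored in the ground truth), so the pipeline's
#'   standardization step is non-trivial.
#' @param seed Integer seed; generation is deterministic given the seed.
#'
#' @return An object of class `generator_config` (validated list).
#' @seealso [generate_cohort()]
#' @export
generator_config <- function(
    n_subjects_per_group = c(sHC = 50, sMCI = 20, cMCI = 15, sAD = 20, cAD = 20),
    n_vr_rois = 15,
    n_qvr_rois = 15,
    visit_months = c(0L, 6L, 12L, 18L, 24L, 36L, 48L, 60L),
    dropout_prob = 0.08,
    slope_vr_range = c(0.02, 0.08),
    vr_negative_prob = 0.8,
    slope_qvr_max = 0.005,
    educ_effect_range = c(-0.02, 0.02),
    latent_dim = 3,
    intercept_sd = 0.5,
    intercept_noise_sd = 0.1,
    obs_noise_sd = 0.2,
    disease_offset = 1.0,
    disease_slope_accel = 0.15,
    affected_fraction = 0.6,
    biomarker_lead_visits = 0L,
    csf_params = default_csf_params(),
    educ_years_range = c(12L, 20L),
    age_baseline_range = c(60, 90),
    destandardize = FALSE,
    seed = 1L) {
  cfg <- list(
    n_subjects_per_group = n_subjects_per_group,
    n_vr_rois = as.integer(n_vr_rois),
    n_qvr_rois = as.integer(n_qvr_rois),
    visit_months = as.integer(visit_months),
    dropout_prob = dropout_prob,
    slope_vr_range = slope_vr_range,
    vr_negative_prob = vr_negative_prob,
    slope_qvr_max = slope_qvr_max,
    educ_effect_range = educ_effect_range,
    latent_dim = as.integer(latent_dim),
    intercept_sd = intercept_sd,
    intercept_noise_sd = intercept_noise_sd,
    obs_noise_sd = obs_noise_sd,
    disease_offset = disease_offset,
    disease_slope_accel = disease_slope_accel,
    affected_fraction = affected_fraction,
    biomarker_lead_visits = as.integer(biomarker_lead_visits),
    csf_params = csf_params,
    educ_years_range = educ_years_range,
    age_baseline_range = age_baseline_range,
    destandardize = isTRUE(destandardize),
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' @noRd
validate_generator_config <- function(cfg) {
  groups <- c("sHC", "sMCI", "cMCI", "sAD", "cAD")
  if (!all(groups %in% names(cfg$n_subjects_per_group)))
    stop_config("n_subjects_per_group must name all of: %s",
                paste(groups, collapse = ", "))
  if (any(cfg$n_subjects_per_group < 0))
    stop_config("n_subjects_per_group must be non-negative")
  if (cfg$n_vr_rois < 0 || cfg$n_qvr_rois < 0 || cfg$n_vr_rois + cfg$n_qvr_rois < 1)
    stop_config("n_vr_rois + n_qvr_rois must be at least 1")
  vm <- cfg$visit_months
  if (length(vm) < 1 || vm[1] != 0L || any(diff(vm) <= 0))
    stop_config("visit_months must be strictly increasing and start at 0")
  if (cfg$dropout_prob < 0 || cfg$dropout_prob >= 1)
    stop_config("dropout_prob must lie in [0, 1)")
  if (length(cfg$slope_vr_range) != 2 || cfg$slope_vr_range[1] > cfg$slope_vr_range[2])
    stop_config("slope_vr_range must be an interval c(lo, hi)")
  if (cfg$n_vr_rois > 0 && cfg$slope_vr_range[1] <= 0.01)
    stop_config("slope_vr_range lower bound must exceed 0.01 SD/year (the vr/qvr boundary)")
  if (cfg$slope_qvr_max < 0 || cfg$slope_qvr_max > 0.005)
    stop_config("slope_qvr_max must lie in [0, 0.005] SD/year")
  if (cfg$latent_dim < 1)
    stop_config("latent_dim must be at least 1")
  for (fld in c("intercept_sd")) {
    if (cfg[[fld]] <= 0) stop_config("%s must be > 0", fld)
  }
  for (fld in c("intercept_noise_sd", "obs_noise_sd", "disease_offset",
                "disease_slope_accel")) {
    if (cfg[[fld]] < 0) stop_config("%s must be >= 0", fld)
  }
  if (cfg$affected_fraction < 0 || cfg$affected_fraction > 1)
    stop_config("affected_fraction must lie in [0, 1]")
  if (cfg$biomarker_lead_visits < 0)
    stop_config("biomarker_lead_visits must be >= 0")
  if (!all(groups %in% names(cfg$csf_params)))
    stop_config("csf_params must name all diagnosis groups")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  subjects/group/gender:",
      paste(sprintf("%s=%d", names(x$n_subjects_per_group),
                    x$n_subjects_per_group), collapse = " "), "\n")
  cat(sprintf("  ROIs: %d variant + %d quasi-variant (latent dim %d)\n",
              x$n_vr_rois, x$n_qvr_rois, x$latent_dim))
  cat(sprintf("  visits (months): %s; dropout %.2f/visit\n",
              paste(x$visit_months, collapse = ","), x$dropout_prob))
  cat(sprintf("  noise: intercept %.2f (+%.2f ROI-specific), observation %.2f SD\n",
              x$intercept_sd, x$intercept_noise_sd, x$obs_noise_sd))
  cat(sprintf("  disease: offset %.2f SD, accel %.2f SD/yr, lead %d visits, seed %d\n",
              x$disease_offset, x$disease_slope_accel,
              x$biomarker_lead_visits, x$seed))
  invisible(x)
}
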