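#' Configuration for a full pipeline run
#'
#' Collects every tunable threshold of the workflow in one place; none of
#' them is hard-coded downstream. Defaults follow the published protocol:
#' CSF cut-offs 192/93 pg/mL, variant threshold 0.01 SD/year with alpha 0.05,
#' radial-kernel SVM with cost 1, and 10 repeated subject-grouped 60/40
#' splits.
#'
#' @param generator A [generator_config()] (used when no cohort file is
#'   supplied).
#' @param cohort_path Optional path to an existing cohort CSV; overrides the
#'   generator.
#' @param genders Genders to process (the whole workflow runs separately per
#'   gender).
#' @param abeta_cutoff,tau_cutoff CSF profile cut-offs (pg/mL).
#' @param vr_threshold,alpha Variant-ROI rule parameters.
#' @param max_components Maximum PLSR components.
#' @param pairs Binary experiments to run.
#' @param variants Feature-set variants (`F1` residuals+age, `F2` adds MMSE
#'   and CDR global).
#' @param label_modes Labelling modes (`current` = subject classification,
#'   `last` = early prediction).
#' @param n_repeats,train_fraction,svm_cost,svm_gamma SVM evaluation
#'   parameters ([train_eval()]).
#' @param seed Integer seed for the stochastic stages.
#' @return List of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       cohort_path = NULL,
                       genders = c("F", "M"),
                       abeta_cutoff = 192, tau_cutoff = 93,
                       vr_threshold = 0.01, alpha = 0.05,
                       max_components = 10,
                       pairs = c("HC-vs-AD", "HC-vs-MCI", "MCI-vs-AD"),
                       variants = c("F1", "F2"),
                       label_modes = c("current", "last"),
                       n_repeats = 10, train_fraction = 0.6,
                       svm_cost = 1, svm_gamma = NULL,
                       seed = 1L) {
  cfg <- list(generator = generator, cohort_path = cohort_path,
              genders = genders, abeta_cutoff = abeta_cutoff,
              tau_cutoff = tau_cutoff, vr_threshold = vr_threshold,
              alpha = alpha, max_components = max_components, pairs = pairs,
              variants = variants, label_modes = label_modes,
              n_repeats = n_repeats, train_fraction = train_fraction,
              svm_cost = svm_cost, svm_gamma = svm_gamma,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full normative-modelling workflow
#'
#' Orchestrates, per gender: cohort generation (or loading), diagnosis and
#' CSF labelling, the null/early cohort split, null-model fitting
#' (standardization, per-ROI mixed models, variant classification, intercept
#' PLSR), residual computation for the early-prediction cohort, and the SVM
#' experiments with the advancement metric for the early-prediction mode.
#' All intermediate artifacts are written under `out_dir` as plain-text
#' files; rerunning with the same configuration reproduces them.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param quiet Suppress progress messages.
#' @return List with `cohort`, `truth` (if generated), `labels`, per-gender
#'   `models`, `residuals`, `reports` (evaluation reports keyed by
#'   `pair|variant|mode|gender`), `advancement`, and `report_table` (tidy
#'   summary data frame).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (is.null(config$cohort_path)) {
    say("generating synthetic cohort (seed %d)", config$generator$seed)
    sim <- generate_cohort(config$generator)
    cohort <- sim$cohort
    truth <- sim$truth
    if (!is.null(out_dir))
      write_cohort(cohort, file.path(out_dir, "cohort.csv"), config$generator)
  } else {
    say("reading cohort from %s", config$cohort_path)
    cohort <- read_cohort(config$cohort_path)
  }

  labels <- label_subjects(cohort, config$abeta_cutoff, config$tau_cutoff)
  if (!is.null(out_dir))
    utils::write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
  parts <- split_cohorts(cohort, labels)
  say("null cohort: %d subjects; early-prediction cohort: %d subjects",
      length(unique(parts$null_cohort$subject_id)),
      length(unique(parts$early_cohort$subject_id)))

  models <- list(); residuals <- list(); reports <- list(); advancement <- list()
  rows <- list()
  for (g in config$genders) {
    null_g <- parts$null_cohort[parts$null_cohort$gender == g, , drop = FALSE]
    early_g <- parts$early_cohort[parts$early_cohort$gender == g, , drop = FALSE]
    if (nrow(null_g) == 0)
      stop_config("no null-cohort subjects for gender %s", g)
    say("[%s] fitting null model on %d subjects", g,
        length(unique(null_g$subject_id)))
    model <- fit_null_model(null_g, threshold = config$vr_threshold,
                            alpha = config$alpha,
                            max_components = config$max_components)
    models[[g]] <- model
    if (!is.null(out_dir))
      write_null_bundle(model, file.path(out_dir, sprintf("null_bundle_%s", g)))
    say("[%s] %d vr / %d qvr ROIs; PLSR ncomp=%d", g, length(model$vr_rois),
        length(model$qvr_rois), model$plsr$ncomp)

    Ev <- cohort_residuals(early_g, model, labels)
    residuals[[g]] <- Ev
    if (!is.null(out_dir)) {
      out <- cbind(attr(Ev, "meta"), as.data.frame(unclass(Ev)))
      utils::write.csv(out, file.path(out_dir, sprintf("residuals_%s.csv", g)),
                       row.names = FALSE)
    }

    for (mode in config$label_modes) {
      for (variant in config$variants) {
        fs <- assemble_features(Ev, variant = variant, label_mode = mode)
        for (pair in config$pairs) {
          key <- sprintf("%s|%s|%s|%s", pair, variant, mode, g)
          rep_k <- tryCatch(
            train_eval(fs, pair = pair, n_repeats = config$n_repeats,
                       train_fraction = config$train_fraction,
                       seed = config$seed, cost = config$svm_cost,
                       gamma = config$svm_gamma),
            normbrain_config_error = function(e) {
              warning(sprintf("experiment %s skipped: %s", key,
                              conditionMessage(e)), call. = FALSE)
              NULL
            })
          if (is.null(rep_k)) next
          reports[[key]] <- rep_k
          m <- rep_k$metrics
          rows[[key]] <- data.frame(
            gender = g, pair = pair, variant = variant, label_mode = mode,
            acc = m$mean[m$metric == "ACC"], sen = m$mean[m$metric == "SEN"],
            spe = m$mean[m$metric == "SPE"], n_repeats = rep_k$n_repeats_used,
            stringsAsFactors = FALSE)
          if (mode == "last") {
            adv <- suppressWarnings(compute_advancement(rep_k))
            advancement[[key]] <- adv
            rows[[key]]$advancement_years <- adv$overall
          } else {
            rows[[key]]$advancement_years <- NA_real_
          }
        }
      }
    }
  }
  report_table <- do.call(rbind, rows)
  rownames(report_table) <- NULL
  if (!is.null(out_dir) && !is.null(report_table))
    utils::write.csv(report_table, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
  list(cohort = cohort, truth = truth, labels = labels, models = models,
       residuals = residuals, reports = reports, advancement = advancement,
       report_table = report_table)
}
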