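# Residual engine: expected-value arithmetic, residual identities,
# column retention, feature assembly.

mock_fit <- function(roi, beta_a, beta_e) {
  structure(list(roi = roi,
                 beta = c(intercept = 0, age = beta_a, educ = beta_e),
                 se_age = 0, p_age = 0, psi = 1, sigma2 = 1, y0 = NULL,
                 n_subjects = 2, n_obs = 4, converged = TRUE,
                 singular = FALSE, degenerate = FALSE),
            class = "lme_fit")
}

test_that("expected values follow the intercept-plus-fixed-effects arithmetic", {
  fits <- list(roi_a = mock_fit("roi_a", -0.05, 0.01))
  y0 <- matrix(2.0, 1, 1, dimnames = list("s1", "roi_a"))
  co <- data.frame(subject_id = "s1", age_years = 80, educ_years = 16)
  expect_equal(unname(predict_expected(y0, co, fits)[1, "roi_a"]),
               2.0 - 0.05 * 80 + 0.01 * 16)  # = -1.84
  # at age 0 the expected value is the intercept itself
  co0 <- data.frame(subject_id = "s1", age_years = 0, educ_years = 0)
  expect_equal(unname(predict_expected(y0, co0, fits)[1, "roi_a"]), 2.0)
  # unknown subject is an error
  co2 <- data.frame(subject_id = "s2", age_years = 70, educ_years = 12)
  expect_error(predict_expected(y0, co2, fits), "s2")
})

test_that("residuals are elementwise differences with strict shape checks", {
  obs <- matrix(c(-2.1, 0.5), 1, 2, dimnames = list(NULL, c("roi_a", "roi_b")))
  exp_ <- matrix(c(-1.84, 0.5), 1, 2, dimnames = list(NULL, c("roi_a", "roi_b")))
  e <- compute_residuals(obs, exp_)
  expect_equal(unname(e[1, "roi_a"]), -0.26)
  expect_equal(unname(e[1, "roi_b"]), 0)
  expect_error(compute_residuals(obs, exp_[, 1, drop = FALSE]), "shapes differ")
  # missing cells propagate
  obs[1, 1] <- NA
  expect_true(is.na(compute_residuals(obs, exp_)[1, 1]))
})

test_that("noise-free healthy subjects have zero residuals end to end", {
  cfg <- generator_config(
    n_subjects_per_group = c(sHC = 14, sMCI = 0, cMCI = 0, sAD = 0, cAD = 0),
    n_vr_rois = 4, n_qvr_rois = 6, dropout_prob = 0,
    obs_noise_sd = 0, intercept_noise_sd = 0, seed = 19,
    csf_params = local({
      p <- default_csf_params(); p$sHC$prob_abnormal <- 0; p
    }))
  sim <- generate_cohort(cfg)
  labels <- label_subjects(sim$cohort)
  # hold out some healthy subjects from the null model; their residuals under
  # the fitted null model must still vanish
  ids <- unique(sim$cohort$subject_id)
  holdout <- ids[c(3, 8, 17)]
  null_co <- sim$cohort[!sim$cohort$subject_id %in% holdout, ]
  model <- fit_null_model(null_co, max_components = 8)
  Ev <- cohort_residuals(sim$cohort[sim$cohort$subject_id %in% holdout, ],
                         model, labels)
  expect_gt(ncol(Ev), 0)
  expect_lt(max(abs(Ev)), 1e-6)
})

test_that("post-conversion residuals track the disease-effect construction", {
  cfg <- generator_config(
    n_subjects_per_group = c(sHC = 40, sMCI = 0, cMCI = 0, sAD = 0, cAD = 30),
    n_vr_rois = 6, n_qvr_rois = 8, dropout_prob = 0,
    obs_noise_sd = 0.05, intercept_noise_sd = 0.05,
    disease_offset = 1.0, disease_slope_accel = 0.2, seed = 29)
  sim <- generate_cohort(cfg)
  labels <- label_subjects(sim$cohort)
  parts <- split_cohorts(sim$cohort, labels)
  nullF <- parts$null_cohort[parts$null_cohort$gender == "F", ]
  model <- fit_null_model(nullF)
  earlyF <- parts$early_cohort[parts$early_cohort$gender == "F" &
                                 grepl("cAD", parts$early_cohort$subject_id), ]
  Ev <- cohort_residuals(earlyF, model, labels)
  meta <- attr(Ev, "meta")
  subj <- sim$truth$subjects
  # residuals on the standardized scale: rescale the generated disease effect
  affected <- intersect(sim$truth$affected_rois, colnames(Ev))
  expect_gt(length(affected), 0)
  err <- c()
  for (i in seq_len(nrow(meta))) {
    s <- subj[subj$subject_id == meta$subject_id[i], ]
    conv_age <- s$age_baseline + s$conversion_month / 12
    if (meta$age_years[i] < conv_age) next
    for (r in affected) {
      scale_r <- model$standardization$scale[model$standardization$roi == r]
      expect_d <- -(cfg$disease_offset +
                      cfg$disease_slope_accel * (meta$age_years[i] - conv_age)) / scale_r
      err <- c(err, Ev[i, r] - expect_d)
    }
  }
  expect_gt(length(err), 50)
  # deviations come only from observation noise and intercept-inference error
  expect_lt(abs(mean(err)), 0.15)
  expect_lt(stats::sd(err), 0.4)
})

test_that("E_v retains variant columns and non-zero quasi-variant columns", {
  e <- matrix(c(0, 0, 0,   0.1, -0.2, 0.3,   0, 0, 0,  0.5, 0.1, -0.1),
              nrow = 3,
              dimnames = list(NULL, c("roi_q1", "roi_q2", "roi_v1", "roi_x")))
  cls <- data.frame(roi = c("roi_q1", "roi_q2", "roi_v1", "roi_x"),
                    label = c("qvr", "qvr", "vr", "excluded"))
  meta <- data.frame(subject_id = c("a", "a", "b"))
  E <- compute_residuals(e, matrix(0, 3, 4, dimnames = dimnames(e)), meta)
  Ev <- build_Ev(E, cls)
  # all-zero qvr dropped; vr kept even when identically zero; excluded dropped
  expect_equal(colnames(Ev), c("roi_q2", "roi_v1"))
  expect_identical(attr(Ev, "meta"), meta)
})

test_that("feature sets have the documented columns and label semantics", {
  e <- matrix(rnorm(12), 4, 3,
              dimnames = list(NULL, c("roi_a", "roi_b", "roi_c")))
  meta <- data.frame(
    subject_id = c("s1", "s1", "s2", "s2"), gender = "F",
    visit_month = c(0, 12, 0, 12), age_years = c(70, 71, 80, 81),
    educ_years = 14, dx_age = c("MCI", "Dementia", "MCI", "MCI"),
    mmse = c(26, 20, 27, 27), cdr_global = c(0.5, 1, 0.5, 0.5),
    dx_last = c("cAD", "cAD", "sMCI", "sMCI"))
  E <- compute_residuals(e, matrix(0, 4, 3, dimnames = dimnames(e)), meta)
  f1 <- assemble_features(E, variant = "F1", label_mode = "current")
  expect_equal(ncol(f1$x), 3 + 1)           # residual columns + age
  expect_equal(as.character(f1$label), c("MCI", "AD", "MCI", "MCI"))
  f2 <- assemble_features(E, variant = "F2", label_mode = "last")
  expect_equal(ncol(f2$x), 3 + 1 + 2)       # + MMSE + CDR global
  # early-prediction labels: every visit of a converter carries the outcome
  expect_equal(as.character(f2$label), c("AD", "AD", "MCI", "MCI"))
  # rows lacking F2 covariates are dropped with a message
  meta2 <- meta; meta2$mmse[2] <- NA
  E2 <- compute_residuals(e, matrix(0, 4, 3, dimnames = dimnames(e)), meta2)
  expect_message(f2b <- assemble_features(E2, "F2", "last"), "dropping 1")
  expect_equal(nrow(f2b$x), 3)
})

test_that("dropping all-zero columns never changes classifier input rows", {
  set.seed(7)
  e <- cbind(matrix(rnorm(40), 20, 2), 0)
  colnames(e) <- c("roi_v1", "roi_q1", "roi_q2")
  cls <- data.frame(roi = colnames(e), label = c("vr", "qvr", "qvr"))
  meta <- data.frame(subject_id = rep(letters[1:10], each = 2),
                     gender = "F", visit_month = rep(c(0, 12), 10),
                     age_years = runif(20, 60, 90), educ_years = 12,
                     dx_age = rep(c("NL", "Dementia"), each = 10),
                     mmse = 28, cdr_global = 0,
                     dx_last = rep(c("sHC", "sAD"), each = 10))
  E <- compute_residuals(e, 0 * e, meta)
  with_all <- assemble_features(E, "F1", "current")
  with_ev <- assemble_features(build_Ev(E, cls), "F1", "current")
  expect_equal(with_ev$x, with_all$x[, colnames(with_ev$x)])
  expect_equal(with_ev$label, with_all$label)
})
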