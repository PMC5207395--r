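# Subject-grouped SVM evaluation: splits, metrics, advancement.

make_feature_set <- function(n_per_class = 20, n_visits = 3, sep = 3,
                             seed = 1, labels = c("HC", "AD")) {
  set.seed(seed)
  n <- 2 * n_per_class * n_visits
  subject_id <- rep(sprintf("s%03d", seq_len(2 * n_per_class)), each = n_visits)
  cls <- rep(rep(labels, each = n_per_class), each = n_visits)
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  x[cls == labels[2], 1:2] <- x[cls == labels[2], 1:2] + sep
  meta <- data.frame(subject_id = subject_id, gender = "F",
                     visit_month = rep(c(0, 12, 24), length.out = n),
                     age_years = runif(n, 60, 90), educ_years = 14,
                     dx_age = ifelse(cls == "AD", "Dementia",
                                     ifelse(cls == "MCI", "MCI", "NL")),
                     mmse = 28, cdr_global = 0,
                     dx_last = ifelse(cls == "AD", "sAD",
                                      ifelse(cls == "MCI", "sMCI", "sHC")))
  structure(list(x = x, label = factor(cls, levels = c("HC", "MCI", "AD")),
                 meta = meta, variant = "F1", label_mode = "current"),
            class = "feature_set")
}

test_that("grouped splits are 60/40 by subject, stratified, and seeded", {
  ids <- rep(sprintf("s%02d", 1:50), each = 4)
  labs <- rep(rep(c("HC", "AD"), each = 25), each = 4)
  splits <- grouped_splits(ids, labs, n_repeats = 10, seed = 7)
  expect_length(splits, 10)
  for (sp in splits) {
    expect_length(sp$train, 30)
    expect_length(sp$test, 20)
    # zero subject leakage, exact
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), unique(ids))
    # stratification: 15 training subjects from each class
    expect_equal(sum(grepl("s0[1-9]$|s1[0-9]$|s2[0-5]$", sp$train)), 15)
  }
  # reproducibility
  expect_identical(splits, grouped_splits(ids, labs, n_repeats = 10, seed = 7))
  expect_false(identical(splits, grouped_splits(ids, labs, n_repeats = 10,
                                                seed = 8)))
  # minimum class size enforcement
  expect_error(grouped_splits(c("a", "b", "c", "d", "e", "f"),
                              c("HC", "HC", "HC", "HC", "HC", "AD")),
               "at least 5")
})

test_that("evaluation metrics match a hand-computed confusion table", {
  truth <- c(rep("AD", 6), rep("HC", 4))
  pred <- c("AD", "AD", "AD", "AD", "HC", "HC", "HC", "HC", "HC", "AD")
  m <- normbrain:::confusion_metrics(truth, pred, positive = "AD")
  # TP=4 FN=2 TN=3 FP=1
  expect_equal(unname(m["acc"]), 100 * 7 / 10)
  expect_equal(unname(m["sen"]), 100 * 4 / 6)
  expect_equal(unname(m["spe"]), 100 * 3 / 4)
})

test_that("well-separated classes are classified nearly perfectly; permuted labels are not", {
  fs <- make_feature_set(sep = 3, seed = 2)
  rep_good <- train_eval(fs, pair = "HC-vs-AD", seed = 5)
  acc <- rep_good$metrics$mean[rep_good$metrics$metric == "ACC"]
  expect_gte(acc, 95)

  # permuting labels at the subject level destroys the signal
  fs_perm <- fs
  set.seed(99)
  subj <- unique(fs$meta$subject_id)
  new_lab <- setNames(sample(as.character(
    tapply(as.character(fs$label), fs$meta$subject_id, `[`, 1)[subj])), subj)
  fs_perm$label <- factor(new_lab[fs_perm$meta$subject_id],
                          levels = levels(fs$label))
  fs_perm$meta$dx_age <- ifelse(fs_perm$label == "AD", "Dementia", "NL")
  rep_null <- train_eval(fs_perm, pair = "HC-vs-AD", seed = 5)
  acc_null <- rep_null$metrics$mean[rep_null$metrics$metric == "ACC"]
  # close to the majority rate (50%): binomial MC noise over test rows
  expect_lt(acc_null, 70)
  expect_gt(acc - acc_null, 20)
})

test_that("advancement follows the first-correct-early-prediction arithmetic", {
  # one converter: clinical conversion at age 76.0; classifier already
  # predicts the AD class at the 74.1-year visit => advancement 1.9 years
  pred <- data.frame(
    repeat_id = 1,
    subject_id = "c1", gender = "F",
    visit_month = c(0, 12, 24), age_years = c(73.0, 74.1, 76.0),
    educ_years = 14, dx_age = c("MCI", "MCI", "Dementia"),
    mmse = 26, cdr_global = 0.5, dx_last = "cAD",
    truth = "AD", pred = c("MCI", "AD", "AD"),
    stringsAsFactors = FALSE)
  report <- structure(list(label_mode = "last", predictions = pred),
                      class = "evaluation_report")
  adv <- compute_advancement(report)
  expect_equal(adv$overall, 76.0 - 74.1, tolerance = 1e-10)
  expect_equal(adv$by_group$gender, "F")
  expect_equal(adv$by_group$age_group, "75-79")

  # a converter never correctly predicted pre-conversion contributes nothing
  pred2 <- pred
  pred2$pred <- c("MCI", "MCI", "AD")
  report2 <- structure(list(label_mode = "last", predictions = pred2),
                       class = "evaluation_report")
  expect_warning(adv2 <- compute_advancement(report2), "no eligible")
  expect_true(is.nan(adv2$overall))

  # non-converters (dx_age already at the final class everywhere) are ignored
  pred3 <- rbind(pred, within(pred, {
    subject_id <- "s9"; dx_age <- "Dementia"; dx_last <- "sAD"
    pred <- "AD"
  }))
  report3 <- structure(list(label_mode = "last", predictions = pred3),
                       class = "evaluation_report")
  adv3 <- compute_advancement(report3)
  expect_equal(nrow(adv3$per_subject), 1)

  # advancement is only defined for the early-prediction mode
  expect_error(compute_advancement(structure(list(label_mode = "current"),
                                             class = "evaluation_report")),
               "last")
})

test_that("a lead in the biomarker signal is recovered as advancement", {
  # evenly spaced annual visits, disease signal 2 visits before conversion
  cfg <- generator_config(
    n_subjects_per_group = c(sHC = 5, sMCI = 25, cMCI = 0, sAD = 0, cAD = 25),
    n_vr_rois = 6, n_qvr_rois = 8,
    visit_months = seq(0L, 60L, 12L), dropout_prob = 0,
    disease_offset = 2.0, disease_slope_accel = 0.3,
    obs_noise_sd = 0.1, biomarker_lead_visits = 2L, seed = 41)
  sim <- generate_cohort(cfg)
  labels <- label_subjects(sim$cohort)
  parts <- split_cohorts(sim$cohort, labels)
  model <- fit_null_model(
    parts$null_cohort[parts$null_cohort$gender == "F", ])
  early <- parts$early_cohort[parts$early_cohort$gender == "F", ]
  Ev <- cohort_residuals(early, model, labels)
  fs <- assemble_features(Ev, variant = "F1", label_mode = "last")
  rep_ <- train_eval(fs, pair = "MCI-vs-AD", seed = 3)
  adv <- compute_advancement(rep_)
  # conversion visits are uniform over visits 2..6; a 2-visit lead is capped
  # at 1 year for conversions at visit 2, so the expected mean lead is
  # slightly below 2 years; require agreement within one visit spacing
  expect_gt(adv$overall, 1.0)
  expect_lt(adv$overall, 3.0)
})
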