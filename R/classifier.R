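#' Subject-grouped, class-stratified train/test splits
#'
#' Longitudinal data has multiple rows per subject; a fair evaluation must
#' keep every observation of a subject on one side of the split. Each of the
#' `n_repeats` random splits assigns 60% (by default) of the subjects of each
#' class to training and the rest to testing, reproducibly given the seed.
#' Subjects whose rows span both classes (possible when labelling by the
#' diagnosis at the visit) are stratified by their majority label.
#'
#' @param subject_ids Per-row subject identifiers.
#' @param labels Per-row class labels (two classes).
#' @param n_repeats Number of independent splits.
#' @param train_fraction Fraction of subjects per class used for training.
#' @param seed Integer seed.
#' @param min_per_class Minimum subjects per class; fewer raises an error.
#' @return List of `n_repeats` lists with elements `train` and `test`
#'   (subject-id character vectors, disjoint by construction).
#' @export
grouped_splits <- function(subject_ids, labels, n_repeats = 10,
                           train_fraction = 0.6, seed = 1L,
                           min_per_class = 5L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction must lie in (0, 1)")
  subject_ids <- as.character(subject_ids)
  labels <- as.character(labels)
  ## majority label per subject (ties: first level encountered)
  subj_label <- vapply(split(labels, subject_ids), function(l)
    names(sort(table(l), decreasing = TRUE))[1], "")
  classes <- unique(subj_label)
  if (length(classes) != 2)
    stop_config("grouped_splits expects exactly 2 classes, got %d",
                length(classes))
  counts <- table(subj_label)
  if (any(counts < min_per_class))
    stop_config("class '%s' has %d subject(s); need at least %d",
                names(counts)[which.min(counts)], min(counts), min_per_class)
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(rep) {
      train <- unlist(lapply(classes, function(cl) {
        ids <- names(subj_label)[subj_label == cl]
        sample(ids, round(train_fraction * length(ids)))
      }), use.names = FALSE)
      list(train = sort(train),
           test = sort(setdiff(names(subj_label), train)))
    })
  })
}

#' @noRd
confusion_metrics <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  c(acc = 100 * (tp + tn) / (tp + tn + fp + fn),
    sen = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    spe = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Train and evaluate a residual-based SVM experiment
#'
#' Runs one binary experiment (`HC-vs-AD`, `HC-vs-MCI` or `MCI-vs-AD`) with a
#' Gaussian radial-kernel support vector machine (misclassification cost
#' `C = 1`) over repeated subject-grouped 60/40 splits. Features are
#' standardized to the training split's statistics before fitting (no test
#' leakage); the kernel width defaults to `1 / (n_features * var(X_train))`.
#' Sensitivity/specificity treat the disease class of the pair as positive.
#' In the early-prediction mode (`label_mode = "last"`) the `MCI-vs-AD` pair
#' contrasts stable-MCI subjects with MCI subjects who later converted to AD
#' (the prodromal discrimination), so stable-AD and HC-converter subjects are
#' excluded from it.
#'
#' @param features A [assemble_features()] feature set.
#' @param pair One of `"HC-vs-AD"`, `"HC-vs-MCI"`, `"MCI-vs-AD"`.
#' @param n_repeats,train_fraction,seed Split parameters (see
#'   [grouped_splits()]).
#' @param cost SVM misclassification cost.
#' @param gamma Radial-kernel width; `NULL` uses the default heuristic.
#' @return Object of class `evaluation_report`: list with `pair`, `variant`,
#'   `label_mode`, `metrics` (mean/SD of ACC, SEN, SPE over repeats),
#'   `confusion` (pooled counts), `n_repeats_used`, `gamma`, and
#'   `predictions` (per-repeat test-row predictions with metadata, for the
#'   advancement computation).
#' @export
train_eval <- function(features, pair = c("HC-vs-AD", "HC-vs-MCI", "MCI-vs-AD"),
                       n_repeats = 10, train_fraction = 0.6, seed = 1L,
                       cost = 1, gamma = NULL) {
  pair <- match.arg(pair)
  classes <- strsplit(pair, "-vs-")[[1]]
  positive <- if ("AD" %in% classes) "AD" else "MCI"

  keep <- features$label %in% classes
  if (features$label_mode == "last" && pair == "MCI-vs-AD")
    keep <- keep & features$meta$dx_last %in% c("sMCI", "cAD")
  x <- features$x[keep, , drop = FALSE]
  lab <- droplevels(features$label[keep])
  meta <- features$meta[keep, , drop = FALSE]
  if (length(unique(lab)) < 2)
    stop_config("experiment %s has fewer than 2 classes after filtering", pair)

  splits <- grouped_splits(meta$subject_id, as.character(lab),
                           n_repeats = n_repeats,
                           train_fraction = train_fraction, seed = seed)
  metrics <- list(); preds <- list(); used <- 0L
  pooled <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  gamma_used <- NA_real_
  for (k in seq_along(splits)) {
    tr <- meta$subject_id %in% splits[[k]]$train
    te <- meta$subject_id %in% splits[[k]]$test
    if (length(unique(lab[tr])) < 2 || sum(te) == 0) next
    ctr <- colMeans(x[tr, , drop = FALSE])
    scl <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, ctr), 2, scl, "/")
    xte <- sweep(sweep(x[te, , drop = FALSE], 2, ctr), 2, scl, "/")
    g <- gamma %||% (1 / (ncol(xtr) * stats::var(as.vector(xtr))))
    gamma_used <- g
    fit <- e1071::svm(xtr, factor(lab[tr]), kernel = "radial",
                      cost = cost, gamma = g, scale = FALSE)
    pred <- stats::predict(fit, xte)
    m <- confusion_metrics(as.character(lab[te]), as.character(pred), positive)
    metrics[[length(metrics) + 1L]] <- m[c("acc", "sen", "spe")]
    pooled <- pooled + m[c("tp", "tn", "fp", "fn")]
    used <- used + 1L
    preds[[length(preds) + 1L]] <- data.frame(
      repeat_id = k, meta[te, , drop = FALSE],
      truth = as.character(lab[te]), pred = as.character(pred),
      stringsAsFactors = FALSE)
  }
  if (used == 0L) stop_config("all splits were degenerate for %s", pair)
  mm <- do.call(rbind, metrics)
  report <- list(
    pair = pair, variant = features$variant, label_mode = features$label_mode,
    positive = positive,
    metrics = data.frame(metric = c("ACC", "SEN", "SPE"),
                         mean = colMeans(mm, na.rm = TRUE),
                         sd = apply(mm, 2, stats::sd, na.rm = TRUE),
                         row.names = NULL),
    confusion = pooled, n_repeats_used = used, gamma = gamma_used,
    predictions = do.call(rbind, preds))
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<evaluation_report %s, %s, %s> %d repeats\n", x$pair, x$variant,
              x$label_mode, x$n_repeats_used))
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %s: %.2f%% (SD %.2f)\n", m$metric[i], m$mean[i], m$sd[i]))
  invisible(x)
}

#' Advancement in years of the early prediction over the clinical diagnosis
#'
#' For each converter subject (a subject with visits whose diagnosis at the
#' visit differs from the coarse class of their last known diagnosis), the
#' clinical conversion age is the age at the first visit where the visit
#' diagnosis reaches the `dx_last` class. If the classifier, evaluated on
#' pre-conversion visits (visit diagnosis still different from the final
#' class), correctly predicted the final class at some earlier visit, the
#' subject's advancement is
#' `conversion age - age at the earliest correct pre-conversion prediction`,
#' averaged over the repeats in which the subject was in the test set.
#' Subject-level advancements are averaged within gender x five-year age
#' strata (stratified by age at clinical conversion); strata with no eligible
#' subjects are absent from the table.
#'
#' @param report An early-prediction (`label_mode = "last"`)
#'   [train_eval()] report.
#' @return List with `by_group` (data frame: `gender`, `age_group`,
#'   `n_subjects`, `advancement_years`, `accuracy`) and `overall` (mean
#'   subject-level advancement in years; `NaN` if no subject is eligible).
#' @export
compute_advancement <- function(report) {
  if (report$label_mode != "last")
    stop_config("advancement requires an early-prediction (label_mode='last') report")
  p <- report$predictions
  p$dx_coarse <- coarse_class(p$dx_age)
  p$final_class <- coarse_class(p$dx_last)

  per_subject <- list()
  for (sid in unique(p$subject_id)) {
    rows <- p[p$subject_id == sid, , drop = FALSE]
    conv_rows <- rows[rows$dx_coarse == rows$final_class, , drop = FALSE]
    pre_rows <- rows[rows$dx_coarse != rows$final_class, , drop = FALSE]
    if (nrow(conv_rows) == 0 || nrow(pre_rows) == 0) next  # not a converter here
    adv_by_rep <- c()
    acc_by_rep <- c()
    for (k in unique(rows$repeat_id)) {
      rk <- rows[rows$repeat_id == k, , drop = FALSE]
      conv_age <- suppressWarnings(
        min(rk$age_years[rk$dx_coarse == rk$final_class]))
      pre <- rk[rk$dx_coarse != rk$final_class & rk$age_years < conv_age, ,
                drop = FALSE]
      if (!is.finite(conv_age) || nrow(pre) == 0) next
      acc_by_rep <- c(acc_by_rep, mean(rk$pred == rk$truth))
      hit <- pre$age_years[pre$pred == pre$final_class]
      if (length(hit) == 0) next  # never correctly predicted before conversion
      adv_by_rep <- c(adv_by_rep, conv_age - min(hit))
    }
    if (length(adv_by_rep) == 0) next
    conv_age_all <- min(conv_rows$age_years)
    per_subject[[sid]] <- data.frame(
      subject_id = sid, gender = rows$gender[1],
      age_group = age_stratum(conv_age_all),
      advancement_years = mean(adv_by_rep),
      accuracy = 100 * mean(acc_by_rep),
      stringsAsFactors = FALSE)
  }
  if (length(per_subject) == 0) {
    warning("no eligible converter subjects for the advancement metric",
            call. = FALSE)
    return(list(by_group = data.frame(gender = character(), age_group = character(),
                                      n_subjects = integer(),
                                      advancement_years = numeric(),
                                      accuracy = numeric()),
                overall = NaN))
  }
  subj <- do.call(rbind, per_subject)
  rownames(subj) <- NULL
  agg <- do.call(rbind, lapply(split(subj, list(subj$gender, subj$age_group),
                                     drop = TRUE), function(g)
    data.frame(gender = g$gender[1], age_group = g$age_group[1],
               n_subjects = nrow(g),
               advancement_years = mean(g$advancement_years),
               accuracy = mean(g$accuracy), stringsAsFactors = FALSE)))
  agg <- agg[order(agg$gender, agg$age_group), , drop = FALSE]
  rownames(agg) <- NULL
  list(by_group = agg, overall = mean(subj$advancement_years),
       per_subject = subj)
}
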