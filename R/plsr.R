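# Kernel PLS core. Classical two-block PLS regression computed with the
# kernel algorithm: at each step the dominant singular vector of X'Y gives
# the X-weight, X is deflated by the score, and regression coefficients are
# accumulated as B_a = W_a (P_a' W_a)^{-1} Q_a'. Equivalent (for prediction)
# to NIPALS PLS2; tested against a brute-force NIPALS oracle.
#' @noRd
kernel_pls_core <- function(Xc, Yc, A) {
  n <- nrow(Xc); p <- ncol(Xc); m <- ncol(Yc)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, m, A)
  B <- vector("list", A)
  X <- Xc
  a_used <- 0L
  for (a in seq_len(A)) {
    S <- crossprod(X, Yc)
    if (sqrt(sum(S^2)) < 1e-12) break
    w <- if (m == 1) S[, 1] else svd(S, nu = 1, nv = 0)$u[, 1]
    w <- w / sqrt(sum(w^2))
    tt <- X %*% w
    tsq <- sum(tt^2)
    if (tsq < 1e-12) break
    P[, a] <- crossprod(X, tt) / tsq
    Q[, a] <- crossprod(Yc, tt) / tsq
    W[, a] <- w
    X <- X - tt %*% t(P[, a, drop = FALSE])
    a_used <- a
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    Qa <- Q[, seq_len(a), drop = FALSE]
    B[[a]] <- Wa %*% solve(crossprod(Pa, Wa), t(Qa))
  }
  list(W = W[, seq_len(a_used), drop = FALSE],
       P = P[, seq_len(a_used), drop = FALSE],
       Q = Q[, seq_len(a_used), drop = FALSE],
       B = B[seq_len(a_used)], n_components = a_used)
}

#' Fit the quasi-variant-to-variant intercept transfer model (kernel PLSR)
#'
#' Regresses the variant-ROI baseline intercepts of the null-cohort subjects
#' on their quasi-variant-ROI intercepts with kernel partial least squares
#' regression on centred data. PLSR suits this map: the predictors are
#' numerous, collinear (they share latent subject-level structure) and noisy,
#' and there are multiple responses modelled jointly. The number of
#' components is chosen by leave-one-out cross-validation, minimizing the
#' root-mean-squared prediction error pooled over all variant responses (a
#' single component count for the whole map).
#'
#' @param qvr_intercepts Numeric matrix/data frame, subjects x quasi-variant
#'   ROIs (predictors). Rows with missing cells in either block are dropped.
#' @param vr_intercepts Numeric matrix/data frame, subjects x variant ROIs
#'   (responses), same subject rows.
#' @param max_components Upper bound on the number of latent components.
#' @param select `"loo"` (default) chooses components by LOO; `"max"` keeps
#'   `max_components` (capped by rank limits).
#' @return Object of class `plsr_model`: predictor/response names, centring
#'   vectors, weight/loading matrices, per-component coefficient matrices,
#'   `ncomp` (selected), and the LOO RMSEP curve (`rmsep`, with the
#'   0-component error as `rmsep0`).
#' @export
fit_plsr <- function(qvr_intercepts, vr_intercepts, max_components = 10,
                     select = c("loo", "max")) {
  select <- match.arg(select)
  if (max_components < 1) stop_config("max_components must be >= 1")
  X <- as.matrix(qvr_intercepts)
  Y <- as.matrix(vr_intercepts)
  if (nrow(X) != nrow(Y))
    stop_config("predictor and response tables must share subject rows")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop_config("predictor and response tables must share subject rows")
  complete <- stats::complete.cases(X) & stats::complete.cases(Y)
  if (sum(!complete) > 0)
    message(sprintf("fit_plsr: dropping %d subject row(s) with missing intercepts",
                    sum(!complete)))
  X <- X[complete, , drop = FALSE]
  Y <- Y[complete, , drop = FALSE]
  n <- nrow(X)
  if (n < 3) stop("fit_plsr requires at least 3 complete subjects", call. = FALSE)

  A <- min(max_components, ncol(X), n - 1L)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  core <- kernel_pls_core(Xc, Yc, A)

  rmsep <- NULL; rmsep0 <- NA_real_; ncomp <- core$n_components
  if (select == "loo") {
    A_cv <- min(A, n - 2L)
    sse <- numeric(A_cv); sse0 <- 0
    for (i in seq_len(n)) {
      xm_i <- colMeans(X[-i, , drop = FALSE])
      ym_i <- colMeans(Y[-i, , drop = FALSE])
      core_i <- kernel_pls_core(sweep(X[-i, , drop = FALSE], 2, xm_i),
                                sweep(Y[-i, , drop = FALSE], 2, ym_i), A_cv)
      x0 <- X[i, ] - xm_i
      sse0 <- sse0 + sum((Y[i, ] - ym_i)^2)
      for (a in seq_len(A_cv)) {
        Ba <- if (a <= core_i$n_components) core_i$B[[a]]
              else core_i$B[[core_i$n_components]]
        pred <- drop(x0 %*% Ba) + ym_i
        sse[a] <- sse[a] + sum((Y[i, ] - pred)^2)
      }
    }
    rmsep <- sqrt(sse / (n * ncol(Y)))  # pooled over subjects and responses
    rmsep0 <- sqrt(sse0 / (n * ncol(Y)))
    ncomp <- min(which.min(rmsep), core$n_components)
  }

  model <- list(
    predictors = colnames(X) %||% paste0("x", seq_len(ncol(X))),
    responses = colnames(Y) %||% paste0("y", seq_len(ncol(Y))),
    xmeans = xm, ymeans = ym,
    W = core$W, P = core$P, Q = core$Q, B = core$B,
    max_rank = core$n_components,
    ncomp = ncomp, rmsep = rmsep, rmsep0 = rmsep0,
    n_subjects = n)
  class(model) <- "plsr_model"
  model
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d predictors -> %d responses, %d subjects; %d component(s) selected",
              length(x$predictors), length(x$responses), x$n_subjects, x$ncomp))
  if (!is.null(x$rmsep))
    cat(sprintf(" (LOO RMSEP %.4g)", x$rmsep[x$ncomp]))
  cat("\n")
  invisible(x)
}

#' Predict variant intercepts from quasi-variant intercepts
#'
#' @param object A [fit_plsr()] model.
#' @param newdata Matrix/data frame of predictor intercepts (columns matching
#'   the model's predictor ROIs), or a single named vector.
#' @param ncomp Number of components (default: the LOO-selected number);
#'   `ncomp = 0` returns the response means.
#' @param ... Unused.
#' @return Matrix of predicted response intercepts (rows as in `newdata`).
#' @export
predict.plsr_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$predictors))
      stop_config("newdata has %d columns; model expects %d",
                  ncol(newdata), length(object$predictors))
    colnames(newdata) <- object$predictors
  }
  missing <- setdiff(object$predictors, colnames(newdata))
  if (length(missing) > 0)
    stop_schema("missing predictor ROI(s): %s", paste(missing, collapse = ", "))
  X <- newdata[, object$predictors, drop = FALSE]
  if (ncomp == 0) {
    out <- matrix(object$ymeans, nrow(X), length(object$ymeans), byrow = TRUE)
  } else {
    if (ncomp > object$max_rank) ncomp <- object$max_rank
    Xc <- sweep(X, 2, object$xmeans)
    out <- Xc %*% object$B[[ncomp]] +
      matrix(object$ymeans, nrow(X), length(object$ymeans), byrow = TRUE)
  }
  dimnames(out) <- list(rownames(X), object$responses)
  out
}

#' Estimate a new subject's quasi-variant baseline intercepts
#'
#' Inverts the age-expected relation for each quasi-variant ROI: with the
#' null model's fixed effects, each observation gives
#' `y0 = y_ij - beta_a * age_ij - beta_e * educ_i`, and the subject's
#' intercept estimate is the mean over their available observations (exact
#' and noise-free observations on the same line give identical values).
#'
#' @param cohort Standardized cohort data frame (new subjects).
#' @param fits Named list of null-model [fit_lme()] results covering the
#'   requested ROIs.
#' @param rois ROI names to estimate (default: all ROIs in `fits`).
#' @return Matrix, subjects x ROIs; `NA` where a subject has no observation
#'   of a ROI.
#' @export
estimate_qvr_intercepts <- function(cohort, fits, rois = names(fits)) {
  missing_fits <- setdiff(rois, names(fits))
  if (length(missing_fits) > 0)
    stop_config("no null-model fit for ROI(s): %s",
                paste(missing_fits, collapse = ", "))
  ids <- unique(cohort$subject_id)
  out <- matrix(NA_real_, length(ids), length(rois),
                dimnames = list(ids, rois))
  for (r in rois) {
    f <- fits[[r]]
    adj <- cohort[[r]] - f$beta[["age"]] * cohort$age_years -
      f$beta[["educ"]] * cohort$educ_years
    means <- tapply(adj, cohort$subject_id, mean, na.rm = TRUE)
    out[names(means), r] <- ifelse(is.nan(means), NA_real_, means)
  }
  skipped <- rowSums(!is.na(out)) == 0
  if (any(skipped))
    message(sprintf("estimate_qvr_intercepts: %d subject(s) with no usable observations",
                    sum(skipped)))
  out
}

#' Infer variant intercepts for new subjects through the null PLSR model
#'
#' Missing predictor cells are imputed with the model's stored predictor
#' means (neutral under centring); the per-subject imputation count is
#' reported. Missing predictor *columns* are an error.
#'
#' @param model A [fit_plsr()] model.
#' @param qvr_intercepts Subjects x quasi-variant-ROI intercept matrix.
#' @return Subjects x variant-ROI matrix of inferred intercepts.
#' @export
infer_vr_intercepts <- function(model, qvr_intercepts) {
  X <- as.matrix(qvr_intercepts)
  missing <- setdiff(model$predictors, colnames(X))
  if (length(missing) > 0)
    stop_schema("missing predictor ROI(s): %s", paste(missing, collapse = ", "))
  X <- X[, model$predictors, drop = FALSE]
  n_imputed <- rowSums(is.na(X))
  if (any(n_imputed > 0)) {
    message(sprintf("infer_vr_intercepts: imputing %d missing cell(s) in %d subject(s) with predictor means",
                    sum(n_imputed), sum(n_imputed > 0)))
    for (j in seq_len(ncol(X)))
      X[is.na(X[, j]), j] <- model$xmeans[j]
  }
  predict(model, X)
}
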