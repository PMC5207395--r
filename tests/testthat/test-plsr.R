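# Kernel PLSR transfer model: oracle equivalence, component selection,
# new-subject intercept estimation.

test_that("kernel PLSR predictions match the brute-force NIPALS oracle", {
  set.seed(101)
  n <- 30; p <- 8; m <- 4
  F0 <- matrix(rnorm(n * 3), n, 3)
  X <- F0 %*% matrix(rnorm(3 * p), 3, p) + 0.2 * matrix(rnorm(n * p), n, p)
  Y <- F0 %*% matrix(rnorm(3 * m), 3, m) + 0.2 * matrix(rnorm(n * m), n, m)
  colnames(X) <- paste0("x", 1:p); colnames(Y) <- paste0("y", 1:m)
  for (a in 1:4) {
    fit <- fit_plsr(X, Y, max_components = a, select = "max")
    oracle <- nipals_pls(X, Y, ncomp = a)
    expect_equal(unname(predict(fit, X, ncomp = a)),
                 unname(oracle$predict(X)), tolerance = 1e-8)
  }
  # single component, single response: equals least squares on the PLS score
  y1 <- Y[, 1, drop = FALSE]
  fit1 <- fit_plsr(X, y1, max_components = 1, select = "max")
  oracle1 <- nipals_pls(X, y1, ncomp = 1)
  expect_equal(unname(predict(fit1, X, ncomp = 1)),
               unname(oracle1$predict(X)), tolerance = 1e-8)
  # and against an explicit regression on the first score
  w <- crossprod(sweep(X, 2, colMeans(X)), y1 - mean(y1))
  w <- w / sqrt(sum(w^2))
  score <- sweep(X, 2, colMeans(X)) %*% w
  lsq <- fitted(lm(y1 ~ score))
  expect_equal(unname(drop(predict(fit1, X, ncomp = 1))), unname(lsq),
               tolerance = 1e-8)
})

test_that("noise-free latent intercepts are recovered exactly at the latent dimension", {
  cfg <- hc_only_config(n_hc = 25, n_vr = 5, n_qvr = 8, seed = 77,
                        obs_noise_sd = 0, intercept_noise_sd = 0,
                        latent_dim = 3)
  tr <- generate_cohort(cfg)$truth
  vr <- tr$roi$roi[tr$roi$type == "vr"]
  qvr <- tr$roi$roi[tr$roi$type == "qvr"]
  fit <- fit_plsr(tr$y0[, qvr], tr$y0[, vr], max_components = 6)
  expect_equal(fit$ncomp, 3)
  expect_lt(fit$rmsep[3], 1e-8)
  pred <- predict(fit, tr$y0[, qvr], ncomp = 3)
  expect_equal(unname(pred), unname(tr$y0[, vr]), tolerance = 1e-8)
  # LOO error at the chosen component count never exceeds its 1-component value
  expect_lte(fit$rmsep[fit$ncomp], fit$rmsep[1])
})

test_that("a response equal to an (orthogonal) predictor column needs one component", {
  set.seed(5)
  # orthogonal centred predictors: the first PLS score is then the response
  # column itself, so a single component reproduces it exactly
  a <- scale(rnorm(20), scale = FALSE)
  b <- resid(lm(rnorm(20) ~ a))
  X <- cbind(a = as.numeric(a), b = as.numeric(b))
  Y <- X[, "a", drop = FALSE]
  colnames(Y) <- "resp"
  fit <- fit_plsr(X, Y, max_components = 2)
  expect_equal(unname(drop(predict(fit, X, ncomp = 1))), unname(X[, "a"]),
               tolerance = 1e-8)
})

test_that("the model is invariant to a common permutation of subject rows", {
  set.seed(9)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("s", 1:20), letters[1:3]))
  Y <- X %*% matrix(rnorm(6), 3, 2) + 0.1 * matrix(rnorm(40), 20, 2)
  colnames(Y) <- c("r1", "r2")
  rownames(Y) <- rownames(X)
  fit1 <- fit_plsr(X, Y, max_components = 3)
  perm <- sample(20)
  fit2 <- fit_plsr(X[perm, ], Y[perm, ], max_components = 3)
  expect_equal(fit2$ncomp, fit1$ncomp)
  expect_equal(fit2$B[[fit2$ncomp]], fit1$B[[fit1$ncomp]], tolerance = 1e-10)
  expect_equal(fit2$rmsep, fit1$rmsep, tolerance = 1e-10)
})

test_that("prediction at the centre returns the response means; contracts hold", {
  set.seed(13)
  X <- matrix(rnorm(45), 15, 3, dimnames = list(NULL, c("q1", "q2", "q3")))
  Y <- X %*% matrix(rnorm(6), 3, 2) + 0.1 * matrix(rnorm(30), 15, 2)
  colnames(Y) <- c("v1", "v2")
  fit <- fit_plsr(X, Y, max_components = 3)
  # feeding back the predictor means (centred zero) gives the response means
  expect_equal(drop(predict(fit, fit$xmeans)), fit$ymeans, tolerance = 1e-10)
  expect_equal(drop(predict(fit, fit$xmeans, ncomp = 0)), fit$ymeans,
               tolerance = 1e-12)
  # missing predictor column is an error naming the ROI
  expect_error(predict(fit, X[, 1:2]), "q3")
  expect_error(fit_plsr(X[1:2, ], Y[1:2, ]), "3 complete subjects")
  expect_error(fit_plsr(X, Y, max_components = 0), "max_components")
})

test_that("new-subject quasi-variant intercepts invert the expected-value relation", {
  # one observation, hand arithmetic: y0 = 0.5 - 0.004*70 - 0 = 0.22
  fits <- list(roi_q = structure(list(
    roi = "roi_q", beta = c(intercept = 0, age = 0.004, educ = 0),
    se_age = 0.001, p_age = 0.5, psi = 1, sigma2 = 1, y0 = NULL,
    n_subjects = 10, n_obs = 40, converged = TRUE, singular = FALSE,
    degenerate = FALSE), class = "lme_fit"))
  co <- data.frame(subject_id = "s1", age_years = 70, educ_years = 16,
                   roi_q = 0.5)
  y0 <- estimate_qvr_intercepts(co, fits, "roi_q")
  expect_equal(y0["s1", "roi_q"], 0.22)
  # two observations on the same true line give the same estimate
  co2 <- data.frame(subject_id = "s1", age_years = c(70, 75),
                    educ_years = 16, roi_q = 0.5 + 0.004 * c(0, 5))
  y02 <- estimate_qvr_intercepts(co2, fits, "roi_q")
  expect_equal(y02["s1", "roi_q"], 0.22)

  # noise-free synthetic subjects: recovered y0 equals generator truth
  cfg <- hc_only_config(n_hc = 10, n_vr = 2, n_qvr = 4, seed = 55,
                        obs_noise_sd = 0, intercept_noise_sd = 0.2)
  sim <- generate_cohort(cfg)
  tr <- sim$truth
  qvr <- tr$roi$roi[tr$roi$type == "qvr"]
  true_fits <- lapply(qvr, function(r) structure(list(
    roi = r, beta = c(intercept = 0,
                      age = tr$roi$slope[tr$roi$roi == r],
                      educ = tr$roi$educ_effect[tr$roi$roi == r]),
    se_age = 0, p_age = 0, psi = 1, sigma2 = 0, y0 = NULL,
    n_subjects = 10, n_obs = 80, converged = TRUE, singular = FALSE,
    degenerate = FALSE), class = "lme_fit"))
  names(true_fits) <- qvr
  est <- estimate_qvr_intercepts(sim$cohort, true_fits, qvr)
  expect_equal(est[rownames(tr$y0), qvr], tr$y0[, qvr], tolerance = 1e-10)
})

test_that("missing predictor cells are imputed neutrally at the centre", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("q1", "q2", "q3")))
  Y <- X %*% matrix(rnorm(3), 3, 1) + 0.05 * rnorm(20)
  colnames(Y) <- "v1"
  fit <- fit_plsr(X, Y, max_components = 3)
  x_new <- X[1:2, ]
  x_new[1, "q2"] <- NA
  expect_message(pred <- infer_vr_intercepts(fit, x_new), "imputing 1")
  x_filled <- X[1:2, ]
  x_filled[1, "q2"] <- fit$xmeans[["q2"]]
  expect_equal(pred, predict(fit, x_filled), tolerance = 1e-12)
})
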