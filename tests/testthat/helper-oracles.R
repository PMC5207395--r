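# Independent oracles and small fixture configurations used across tests.

# Brute-force NIPALS PLS2 regression (textbook form, with Y deflation).
# Deliberately independent of the package's kernel-algorithm implementation:
# iterative power-method weights, score-by-score deflation of both blocks.
nipals_pls <- function(X, Y, ncomp, tol = 1e-24, maxit = 10000) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  xm <- colMeans(X); ym <- colMeans(Y)
  E <- sweep(X, 2, xm); F0 <- sweep(Y, 2, ym)
  Fm <- F0
  p <- ncol(X); m <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, m, ncomp); TT <- matrix(0, nrow(X), ncomp)
  for (a in seq_len(ncomp)) {
    u <- Fm[, which.max(apply(Fm, 2, stats::var)), drop = FALSE]
    w_old <- rep(0, p)
    for (it in seq_len(maxit)) {
      w <- crossprod(E, u); w <- w / sqrt(sum(w^2))
      tt <- E %*% w
      q <- crossprod(Fm, tt) / c(crossprod(tt))
      u <- Fm %*% q / c(crossprod(q))
      if (sum((w - w_old)^2) < tol) break
      w_old <- w
    }
    tt <- E %*% w
    pvec <- crossprod(E, tt) / c(crossprod(tt))
    q <- crossprod(Fm, tt) / c(crossprod(tt))
    E <- E - tt %*% t(pvec)
    Fm <- Fm - tt %*% t(q)
    W[, a] <- w; P[, a] <- pvec; Q[, a] <- q; TT[, a] <- tt
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  list(B = B, xmeans = xm, ymeans = ym,
       predict = function(Xnew) {
         sweep(as.matrix(Xnew), 2, xm) %*% B +
           matrix(ym, nrow(as.matrix(Xnew)), m, byrow = TRUE)
       })
}

# Pooled ordinary least squares oracle for the noise-free mixed-model case.
ols_slope <- function(y, age, educ) {
  if (stats::sd(educ) > 1e-12) unname(coef(lm(y ~ age + educ))["age"])
  else unname(coef(lm(y ~ age))["age"])
}

# A small healthy-controls-only configuration for parameter-recovery tests.
hc_only_config <- function(n_hc = 40, n_vr = 5, n_qvr = 5, seed = 1,
                           dropout_prob = 0, ...) {
  generator_config(
    n_subjects_per_group = c(sHC = n_hc, sMCI = 0, cMCI = 0, sAD = 0, cAD = 0),
    n_vr_rois = n_vr, n_qvr_rois = n_qvr, dropout_prob = dropout_prob,
    seed = seed, ...)
}

# A compact all-groups configuration for pipeline-level tests.
small_pipeline_config <- function(seed = 1, ...) {
  generator_config(
    n_subjects_per_group = c(sHC = 20, sMCI = 8, cMCI = 6, sAD = 8, cAD = 8),
    n_vr_rois = 8, n_qvr_rois = 8, seed = seed, ...)
}
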