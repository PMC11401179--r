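#' Rank-based inverse-normal (quantile) normalization
#'
#' Transforms each column to Gaussian scores qnorm((rank - 0.5) / N), with
#' ties averaged. Monotone per column and invariant to any monotone
#' transform of the input.
#'
#' @param Y N x P numeric matrix of raw scores
#' @return matrix of the same shape with marginally Gaussian columns
#' @export
quantile_normalize <- function(Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  out <- apply(Y, 2, function(col) {
    if (length(unique(col)) < 3) stop("column with fewer than 3 distinct values cannot be quantile normalized")
    qnorm((rank(col, ties.method = "average") - 0.5) / n)
  })
  dimnames(out) <- dimnames(Y)
  out
}

#' Impute missing behavioral scores and covariates
#'
#' Behavioral missing values are set to the column median across subjects;
#' a missing medication dose is set to zero (the study convention for
#' subjects with zero lifetime antipsychotic exposure).
#'
#' @param scores N x P behavioral matrix/data.frame, may contain NA
#' @param covariates N x q covariate matrix/data.frame, may contain NA in
#'   the medication column
#' @param medication_col name or index of the medication-dose covariate
#' @return list with completed `scores` and `covariates` and the count of
#'   imputed cells in `n_imputed`
#' @export
impute_behavior <- function(scores, covariates = NULL, medication_col = "medication") {
  scores <- as.matrix(scores)
  n_imp <- 0L
  for (j in seq_len(ncol(scores))) {
    miss <- is.na(scores[, j])
    if (any(miss)) {
      if (mean(miss) >= 0.1) stop("more than 10% missing in a behavioral column")
      scores[miss, j] <- median(scores[!miss, j])
      n_imp <- n_imp + sum(miss)
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (medication_col %in% colnames(covariates) || is.numeric(medication_col)) {
      miss <- is.na(covariates[[medication_col]])
      if (any(miss)) {
        covariates[[medication_col]][miss] <- 0
        n_imp <- n_imp + sum(miss)
      }
    }
    if (anyNA(covariates)) stop("covariates other than medication dose may not be missing")
  }
  list(scores = scores, covariates = covariates, n_imputed = n_imp)
}

#' Project fixed effects out of the model
#'
#' For Y = XB + C + E with Vec(C) ~ N(0, Sigma_c (x) R) and
#' Vec(E) ~ N(0, Sigma_e (x) I), multiplying by an orthonormal basis U of
#' the orthogonal complement of span([1 X]) removes the fixed effects
#' exactly: the transformed model Y~ = C~ + E~ has kernel U'RU and no B.
#' An intercept is always appended to X.
#'
#' @param Y N x P outcome matrix
#' @param X N x q covariate matrix, or NULL for intercept only
#' @param R N x N similarity matrix
#' @return list with transformed `Y` ((N-rank) x P), `R`, the basis `U`
#'   and the rank of the design
#' @export
project_out_covariates <- function(Y, X, R) {
  Y <- as.matrix(Y); R <- as.matrix(R)
  n <- nrow(Y)
  stopifnot(nrow(R) == n, ncol(R) == n)
  Xf <- if (is.null(X)) matrix(1, n, 1) else cbind(intercept = 1, as.matrix(X))
  qx <- qr(Xf)
  if (qx$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qx$pivot[(qx$rank + 1):ncol(Xf)]]
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  U <- qr.Q(qx, complete = TRUE)[, (qx$rank + 1):n, drop = FALSE]
  Rt <- crossprod(U, R %*% U)
  list(Y = crossprod(U, Y), R = (Rt + t(Rt)) / 2, U = U, rank = qx$rank)
}

#' Moment-matching variance-component fit
#'
#' Estimates Sigma_c and Sigma_e in the transformed model Y = C + E,
#' Vec(C) ~ N(0, Sigma_c (x) R), Vec(E) ~ N(0, Sigma_e (x) I), by moment
#' matching: with tau = Tr(R)/N, kappa = Tr(R^2)/N, nu = N(kappa - tau^2),
#'
#'   Sigma_c = Y'(R - tau I)Y / nu,   Sigma_e = Y'(kappa I - tau R)Y / nu.
#'
#' Variance explained is the trace ratio M = Tr(Sigma_c) /
#' (Tr(Sigma_c) + Tr(Sigma_e)), per measure M_i from the diagonals.
#' Reported fractions are clipped to [0, 1]. The one-sided Wald test of
#' M > 0 uses the unclipped ratio and a score-type standard error: the
#' exact Gaussian quadratic-form variance of the ratio evaluated at the
#' null (Sigma_c = 0) with the fitted total covariance plugged in, so the
#' p-value is calibrated against the same reference the permutation test
#' samples. `SE` and `SE_i` are delta-method standard errors at the
#' estimates (plug-in), for error bars and contrasts.
#'
#' @param Yt transformed outcome matrix from [project_out_covariates]
#' @param Rt transformed similarity matrix
#' @return object of class `varcomp_fit`: `Sigma_c`, `Sigma_e`, `tau`,
#'   `kappa`, `nu`, `M` and `M_i` (clipped), `M_raw` and `M_i_raw`,
#'   `SE`, `SE_i`, `p_wald`, `p_wald_i`
#' @export
fit_varcomp <- function(Yt, Rt) {
  Yt <- as.matrix(Yt); Rt <- as.matrix(Rt)
  n <- nrow(Yt); P <- ncol(Yt)
  stopifnot(nrow(Rt) == n, ncol(Rt) == n)
  Rt <- (Rt + t(Rt)) / 2
  tau <- sum(diag(Rt)) / n
  kap <- sum(Rt * Rt) / n
  nu <- n * (kap - tau^2)
  if (nu <= 1e-8)
    stop("unidentifiable model: similarity matrix is numerically proportional to the identity (nu ~ 0)")
  RY <- Rt %*% Yt
  Sc <- crossprod(Yt, RY - tau * Yt) / nu
  Se <- (kap * crossprod(Yt) - tau * crossprod(Yt, RY)) / nu
  Sc <- (Sc + t(Sc)) / 2; Se <- (Se + t(Se)) / 2
  Tc <- sum(diag(Sc)); Te <- sum(diag(Se))
  M_raw <- Tc / (Tc + Te)
  mi_raw <- diag(Sc) / (diag(Sc) + diag(Se))

  # delta-method variance of the trace ratio, from the exact covariance of
  # Gaussian quadratic forms under the plug-in (Sigma_c, Sigma_e):
  # Cov(TrY'AY, TrY'BY) = 2[Tr(Sc^2)Tr(ARBR) + 2Tr(ScSe)Tr(ARB) + Tr(Se^2)Tr(AB)]
  # where A = R - tau I and B = kappa I - tau R commute with R, so all
  # traces are spectral sums.
  ev <- eigen(Rt, symmetric = TRUE, only.values = TRUE)$values
  f <- ev - tau
  g <- kap - tau * ev
  qcov <- function(av, bv, c2, ce, e2)
    2 * (c2 * sum(av * bv * ev^2) + 2 * ce * sum(av * bv * ev) + e2 * sum(av * bv))
  ratio_var <- function(tc, te, c2, ce, e2) {
    vtc <- qcov(f, f, c2, ce, e2) / nu^2
    vte <- qcov(g, g, c2, ce, e2) / nu^2
    cte <- qcov(f, g, c2, ce, e2) / nu^2
    s <- tc + te
    max((te^2 * vtc - 2 * tc * te * cte + tc^2 * vte) / s^4, 0)
  }
  SE <- sqrt(ratio_var(Tc, Te, sum(Sc * Sc), sum(Sc * Se), sum(Se * Se)))
  SE_i <- vapply(seq_len(P), function(i)
    sqrt(ratio_var(Sc[i, i], Se[i, i], Sc[i, i]^2, Sc[i, i] * Se[i, i], Se[i, i]^2)),
    numeric(1))
  # score-type Wald test: the variance of the trace ratio is evaluated at
  # the null (Sigma_c = 0) with the total covariance St = Sc + Se plugged
  # in, mirroring the reference distribution the permutation test draws
  # from; the plug-in SE above is reported for error bars.
  St <- Sc + Se
  s_tot <- Tc + Te
  var0 <- 2 * sum(St * St) * sum(f^2) / nu^2
  SE0 <- sqrt(var0) / s_tot
  if (SE0 <= 0) stop("Wald SE is zero")
  p_wald <- 1 - pnorm(M_raw / SE0)
  SE0_i <- sqrt(2 * diag(St)^2 * sum(f^2) / nu^2) / (diag(Sc) + diag(Se))
  p_wald_i <- ifelse(SE0_i > 0, 1 - pnorm(mi_raw / SE0_i), NA_real_)
  nm <- colnames(Yt)
  structure(list(Sigma_c = Sc, Sigma_e = Se, tau = tau, kappa = kap, nu = nu,
                 M = min(max(M_raw, 0), 1), M_raw = M_raw,
                 M_i = setNames(pmin(pmax(mi_raw, 0), 1), nm),
                 M_i_raw = setNames(mi_raw, nm),
                 SE = SE, SE_i = setNames(SE_i, nm),
                 SE_null = SE0, SE_null_i = setNames(SE0_i, nm),
                 p_wald = p_wald, p_wald_i = setNames(p_wald_i, nm),
                 n = n, P = P),
            class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat(sprintf("varcomp_fit: M = %.3f (SE %.3f, p-Wald %.4g), n = %d, P = %d\n",
              x$M, x$SE, x$p_wald, x$n, x$P))
  if (x$P > 1) {
    cat("per-measure variance explained:\n")
    print(round(x$M_i, 3))
  }
  invisible(x)
}

#' Permutation test of the variance-component model
#'
#' Applies the same random permutation to the rows and columns of the
#' transformed similarity matrix and recomputes the (unclipped) trace
#' ratio; p = (1 + #\{M_perm >= M_obs\}) / (n_perm + 1). tau, kappa and nu
#' are permutation invariant, so each permutation costs one weighted sum.
#'
#' @param Yt,Rt transformed model from [project_out_covariates]
#' @param n_perm number of permutations (>= 100, default 1000)
#' @param seed RNG seed
#' @return permutation p-value
#' @export
permutation_p <- function(Yt, Rt, n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 100)
  Yt <- as.matrix(Yt); Rt <- as.matrix(Rt)
  n <- nrow(Yt)
  tau <- sum(diag(Rt)) / n
  kap <- sum(Rt * Rt) / n
  nu <- n * (kap - tau^2)
  if (nu <= 1e-8) stop("unidentifiable model (nu ~ 0)")
  G <- tcrossprod(Yt)
  trG <- sum(diag(G))
  ratio <- function(s) (s - tau * trG) / ((s - tau * trG) + (kap * trG - tau * s))
  obs <- ratio(sum(Rt * G))
  set.seed(seed)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (ratio(sum(Rt[p, p] * G)) >= obs) cnt <- cnt + 1L
  }
  (1 + cnt) / (n_perm + 1)
}

#' Fit the ESE-behavior model for one similarity matrix
#'
#' Convenience wrapper: projects covariates out, fits the moment-matching
#' estimator and runs the permutation test.
#'
#' @param Y N x P behavioral matrix (quantile-normalized)
#' @param X N x q covariates or NULL
#' @param R N x N similarity matrix (or a `similarity_matrix`)
#' @param n_perm permutations for p-Perm
#' @param seed RNG seed
#' @return a `varcomp_fit` with an extra `p_perm` field
#' @export
ese_variance_model <- function(Y, X, R, n_perm = 1000L, seed = 1L) {
  if (inherits(R, "similarity_matrix")) R <- R$R
  pr <- project_out_covariates(Y, X, R)
  fit <- fit_varcomp(pr$Y, pr$R)
  fit$p_perm <- permutation_p(pr$Y, pr$R, n_perm = n_perm, seed = seed)
  fit
}

#' Univariate variance-component fit
#'
#' The same estimator with a single outcome (P = 1), as used for clinical
#' symptom scales. Identical to the multivariate fit on a one-column Y.
#'
#' @param y length-N outcome vector
#' @param X covariates or NULL
#' @param R N x N similarity matrix
#' @return list with `m` (clipped fraction), `m_raw`, `SE`, `p_wald`
#' @export
univariate_fit <- function(y, X, R) {
  if (inherits(R, "similarity_matrix")) R <- R$R
  pr <- project_out_covariates(cbind(y = y), X, R)
  fit <- fit_varcomp(pr$Y, pr$R)
  list(m = fit$M, m_raw = fit$M_raw, SE = fit$SE, p_wald = fit$p_wald)
}

# resample-safe refit used by the bootstrap: subjects `idx` (possibly with
# duplicates), similarity given as a full-sample matrix to subset
refit_subset <- function(Y, X, Rfull, idx) {
  Rs <- Rfull[idx, idx, drop = FALSE]
  diag(Rs) <- 1
  pr <- project_out_covariates(Y[idx, , drop = FALSE],
                               if (is.null(X)) NULL else X[idx, , drop = FALSE], Rs)
  fit_varcomp(pr$Y, pr$R)
}

#' Bootstrap contrast of HEN vs LEN variance explained
#'
#' Resamples patients with replacement, rebuilds both similarity matrices
#' from the resampled entropy vectors, refits both models, and forms
#' bias-corrected percentile confidence intervals of the difference
#' (HEN - LEN) in variance explained, overall and per measure, at level
#' `alpha / n_tests` (Bonferroni). Degenerate resamples (similarity
#' numerically proportional to the identity, or a rank-deficient resampled
#' design) are redrawn up to 10 times and counted.
#'
#' @param Y N x P behavioral matrix
#' @param X covariates or NULL
#' @param es `entropy_set` (or subjects x edges matrix) for the analysis
#'   group
#' @param mask_hen,mask_len the two [template_mask]s
#' @param n_boot bootstrap replicates (>= 1000 recommended)
#' @param alpha family error level (default 0.05)
#' @param n_tests Bonferroni divisor (default P + 1: overall plus each
#'   measure)
#' @param seed RNG seed
#' @param group analysis group when `es` is an `entropy_set`
#' @return object of class `ese_contrast`: `estimate` (named vector,
#'   overall + measures), `ci` (2-column matrix), `excludes_zero`,
#'   `replicates`, `n_redrawn`, `se_boot`
#' @export
bootstrap_contrast <- function(Y, X, es, mask_hen, mask_len,
                               n_boot = 1000L, alpha = 0.05, n_tests = NULL,
                               seed = 1L, group = "patient") {
  Y <- as.matrix(Y)
  n <- nrow(Y); P <- ncol(Y)
  if (is.null(n_tests)) n_tests <- P + 1L
  R1 <- build_similarity(es, mask_hen, group = group)$R
  R2 <- build_similarity(es, mask_len, group = group)$R
  stat <- function(idx) {
    f1 <- refit_subset(Y, X, R1, idx)
    f2 <- refit_subset(Y, X, R2, idx)
    c(overall = f1$M - f2$M, f1$M_i - f2$M_i)
  }
  obs <- stat(seq_len(n))
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, length(obs),
                 dimnames = list(NULL, names(obs)))
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    for (attempt in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(stat(idx), error = function(e) NULL)
      if (!is.null(v)) break
      n_redrawn <- n_redrawn + 1L
    }
    if (is.null(v)) stop("bootstrap resample degenerate after 10 redraws")
    reps[b, ] <- v
  }
  a <- alpha / n_tests
  ci <- t(vapply(seq_along(obs), function(k) {
    prop <- mean(reps[, k] < obs[k])
    z0 <- qnorm(min(max(prop, 1 / (n_boot + 1)), n_boot / (n_boot + 1)))
    lv <- pnorm(2 * z0 + qnorm(a / 2))
    uv <- pnorm(2 * z0 + qnorm(1 - a / 2))
    quantile(reps[, k], c(lv, uv), names = FALSE)
  }, numeric(2)))
  dimnames(ci) <- list(names(obs), c("lower", "upper"))
  structure(list(estimate = obs, ci = ci,
                 excludes_zero = ci[, 1] > 0 | ci[, 2] < 0,
                 replicates = reps, n_redrawn = n_redrawn,
                 se_boot = apply(reps, 2, sd),
                 alpha = alpha, n_tests = n_tests, method = "bootstrap-BC"),
            class = "ese_contrast")
}

#' Jackknife contrast of HEN vs LEN variance explained
#'
#' Leave-one-patient-out version of [bootstrap_contrast]: normal-theory
#' confidence intervals from the jackknife variance, with the same
#' Bonferroni adjustment.
#'
#' @inheritParams bootstrap_contrast
#' @return an `ese_contrast` object (with `se_jack` instead of `se_boot`)
#' @export
jackknife_contrast <- function(Y, X, es, mask_hen, mask_len,
                               alpha = 0.05, n_tests = NULL, group = "patient") {
  Y <- as.matrix(Y)
  n <- nrow(Y); P <- ncol(Y)
  if (n < 10) stop("jackknife needs at least 10 subjects")
  if (is.null(n_tests)) n_tests <- P + 1L
  R1 <- build_similarity(es, mask_hen, group = group)$R
  R2 <- build_similarity(es, mask_len, group = group)$R
  stat <- function(idx) {
    f1 <- refit_subset(Y, X, R1, idx)
    f2 <- refit_subset(Y, X, R2, idx)
    c(overall = f1$M - f2$M, f1$M_i - f2$M_i)
  }
  obs <- stat(seq_len(n))
  loo <- t(vapply(seq_len(n), function(i) stat(setdiff(seq_len(n), i)),
                  numeric(length(obs))))
  se <- sqrt((n - 1) / n * colSums(sweep(loo, 2, colMeans(loo))^2))
  z <- qnorm(1 - (alpha / n_tests) / 2)
  ci <- cbind(lower = obs - z * se, upper = obs + z * se)
  rownames(ci) <- names(obs)
  structure(list(estimate = obs, ci = ci,
                 excludes_zero = ci[, 1] > 0 | ci[, 2] < 0,
                 replicates = loo, se_jack = setNames(se, names(obs)),
                 alpha = alpha, n_tests = n_tests, method = "jackknife"),
            class = "ese_contrast")
}

#' @export
print.ese_contrast <- function(x, ...) {
  cat(sprintf("ese_contrast (%s), alpha = %g / %d tests\n",
              x$method, x$alpha, x$n_tests))
  out <- data.frame(estimate = round(x$estimate, 3),
                    lower = round(x$ci[, 1], 3), upper = round(x$ci[, 2], 3),
                    excludes_zero = x$excludes_zero)
  print(out)
  invisible(x)
}

#' Edgewise variance explained
#'
#' Univariate (per-edge) variant: for each template edge, the similarity
#' kernel is the rank-one product of patientwise standardized ESE values
#' with the diagonal replaced by 1. The model is fitted measure by measure
#' (the moment estimator is column-separable) and the edge value is the
#' mean of the per-measure clipped fractions.
#'
#' @param Y N x P behavioral matrix
#' @param X covariates or NULL
#' @param es `entropy_set` or subjects x edges matrix
#' @param mask a [template_mask]
#' @param group analysis group
#' @return data.frame with `edge` (canonical position) and `value`
#'   (mean variance explained; NA for degenerate edges)
#' @export
edgewise_variance <- function(Y, X, es, mask, group = "patient") {
  stopifnot(inherits(mask, "template_mask"))
  Y <- as.matrix(Y)
  m <- entropy_matrix(es, group)
  n <- nrow(Y)
  stopifnot(nrow(m) == n)
  Xf <- if (is.null(X)) matrix(1, n, 1) else cbind(1, as.matrix(X))
  qx <- qr(Xf)
  U <- qr.Q(qx, complete = TRUE)[, (qx$rank + 1):n, drop = FALSE]
  Yt <- crossprod(U, Y)
  nt <- ncol(U)
  vals <- vapply(mask$edges, function(e) {
    x <- m[, e]
    if (anyNA(x) || sd_pop(x) == 0) return(NA_real_)
    z <- (x - mean(x)) / sd_pop(x)
    u <- crossprod(U, z)
    Rt <- tcrossprod(u) + crossprod(U, U * (1 - z^2))
    tau <- sum(diag(Rt)) / nt
    kap <- sum(Rt * Rt) / nt
    nu <- nt * (kap - tau^2)
    if (nu <= 1e-8) return(NA_real_)
    RY <- Rt %*% Yt
    qc <- colSums(Yt * RY) - tau * colSums(Yt^2)
    qe <- kap * colSums(Yt^2) - tau * colSums(Yt * RY)
    mean(pmin(pmax(qc / (qc + qe), 0), 1))
  }, numeric(1))
  data.frame(edge = mask$edges, value = vals)
}
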