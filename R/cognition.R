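#' First principal component of the cognitive battery
#'
#' Eigendecomposition of the correlation matrix of the (whole-sample)
#' behavioral scores. The first component is oriented so that the loading
#' sum is positive; an all-positive first component indicates shared
#' variance across tasks ("integration").
#'
#' @param Y N x P score matrix (whole sample, patients + controls)
#' @return object of class `pca_result`: `loadings` (unit-norm first
#'   eigenvector), `var_explained` (fraction of total variance)
#' @export
first_pc <- function(Y) {
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) > ncol(Y))
  e <- eigen(cor(Y), symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  structure(list(loadings = setNames(v, colnames(Y)),
                 var_explained = e$values[1] / ncol(Y)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: PC1 explains %.1f%% of the variance\n",
              100 * x$var_explained))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Bootstrap contrast of PC1 loadings between measure groups
#'
#' Resamples subjects, recomputes the first principal component with a
#' fixed orientation (aligned to the observed component, loading sum
#' positive), and forms a percentile confidence interval of
#' mean(loadings in group A) - mean(loadings in group B).
#'
#' @param Y N x P score matrix
#' @param group_a,group_b disjoint character vectors of measure names (or
#'   column indices)
#' @param n_boot bootstrap replicates (default 2000)
#' @param seed RNG seed
#' @param conf confidence level (default 0.95)
#' @return list: `difference`, `ci`, `replicates`, `loadings` (observed)
#' @export
loading_contrast <- function(Y, group_a, group_b, n_boot = 2000L, seed = 1L,
                             conf = 0.95) {
  Y <- as.matrix(Y)
  if (is.character(group_a)) group_a <- match(group_a, colnames(Y))
  if (is.character(group_b)) group_b <- match(group_b, colnames(Y))
  stopifnot(!anyNA(group_a), !anyNA(group_b),
            length(intersect(group_a, group_b)) == 0,
            length(group_a) >= 1, length(group_b) >= 1)
  obs <- first_pc(Y)
  v0 <- obs$loadings
  diff_of <- function(v) mean(v[group_a]) - mean(v[group_b])
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(Y), replace = TRUE)
    v <- tryCatch(first_pc(Y[idx, , drop = FALSE])$loadings,
                  error = function(e) NULL)
    if (is.null(v)) return(NA_real_)
    if (sum(v * v0) < 0) v <- -v  # align to the observed component
    diff_of(v)
  }, numeric(1))
  reps <- reps[!is.na(reps)]
  a <- (1 - conf) / 2
  list(difference = diff_of(v0),
       ci = quantile(reps, c(a, 1 - a), names = FALSE),
       replicates = reps, loadings = v0, conf = conf)
}
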