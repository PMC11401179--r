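#' Sample entropy parameters
#'
#' @param m embedding dimension (default 2)
#' @param eps tolerance scale; the matching tolerance is `r = eps * sd(x)`
#'   with the population (1/N) standard deviation (default 0.20)
#' @return list with class `sampen_params`
#' @export
sampen_params <- function(m = 2L, eps = 0.20) {
  stopifnot(m >= 1, eps > 0)
  structure(list(m = as.integer(m), eps = eps), class = "sampen_params")
}

#' Sample entropy of a series
#'
#' SampEn(m, eps) is the negative log of the conditional probability that
#' sequences matching for m points (Chebyshev distance <= r, boundary
#' inclusive) also match for m + 1 points, with tolerance r = eps * sigma
#' (population sd). Template vectors run over i = 1..N-m for both lengths.
#' Lower values indicate more regular, self-similar dynamics.
#'
#' @param x numeric vector, length > m + 1
#' @param params a [sampen_params] object
#' @return nonnegative scalar in nats, or `NA` when no template pair
#'   matches at either length (undefined entropy, flagged not infinite)
#' @export
#' @examples
#' sample_entropy(rep(1, 50))            # constant signal -> 0
#' sample_entropy(sin(seq(0, 20, 0.1)))  # regular -> small
sample_entropy <- function(x, params = sampen_params()) {
  stopifnot(inherits(params, "sampen_params"), is.numeric(x))
  .sampen_cpp(as.numeric(x), params$m, params$eps)
}

#' Edgewise sample entropy
#'
#' Applies [sample_entropy] to every edge column of each subject's windowed
#' correlation timeseries. Edges with undefined entropy (no matching
#' template pairs) are returned as `NA` and counted per subject; downstream
#' template construction skips them.
#'
#' @param ed an `edge_dynamics` object from [sliding_window_correlation]
#' @param params a [sampen_params] object
#' @return object of class `entropy_set`: a subjects x edges matrix
#'   `values`, the edge index, the parameters, and the per-subject count
#'   of undefined edges
#' @export
edge_entropy <- function(ed, params = sampen_params()) {
  stopifnot(inherits(ed, "edge_dynamics"))
  nw <- nrow(ed$subjects[[1]])
  if (nw <= params$m + 1)
    stop(sprintf("window count (%d) must exceed m + 1 (%d)", nw, params$m + 1))
  vals <- t(vapply(ed$subjects, function(m) .sampen_cols_cpp(m, params$m, params$eps),
                   numeric(nrow(ed$edge_index))))
  rownames(vals) <- names(ed$subjects)
  colnames(vals) <- ed$edge_index$name
  structure(list(values = vals, edge_index = ed$edge_index, params = params,
                 group = ed$group,
                 n_undefined = rowSums(is.na(vals))),
            class = "entropy_set")
}

#' @export
print.entropy_set <- function(x, ...) {
  cat(sprintf("entropy_set: %d subjects x %d edges (m = %d, eps = %g); %d undefined values\n",
              nrow(x$values), ncol(x$values), x$params$m, x$params$eps,
              sum(x$n_undefined)))
  invisible(x)
}
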