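#' Group-mean edge entropy
#'
#' Elementwise mean ESE across a template group (the healthy controls in
#' the study design), skipping undefined (NA) values. Edges undefined in
#' more than half of the group are dropped (set to NA) with a message.
#'
#' @param es an `entropy_set` from [edge_entropy], or a subjects x edges
#'   numeric matrix
#' @param group which subjects to average when `es` is an `entropy_set`
#'   ("control", "patient" or "all")
#' @return named numeric vector, one mean per edge (NA = dropped)
#' @export
group_mean_entropy <- function(es, group = "control") {
  m <- entropy_matrix(es, group)
  if (nrow(m) < 2) stop("need at least 2 subjects to build a template")
  frac_na <- colMeans(is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  drop <- frac_na > 0.5
  if (any(drop)) {
    message(sprintf("dropping %d edges undefined in > 50%% of the group", sum(drop)))
    mu[drop] <- NA_real_
  }
  mu[is.nan(mu)] <- NA_real_
  mu
}

# extract a subjects x edges matrix from an entropy_set or pass a matrix through
entropy_matrix <- function(es, group = "all") {
  if (inherits(es, "entropy_set")) {
    m <- es$values
    if (group != "all") m <- m[es$group[rownames(m)] == group, , drop = FALSE]
    m
  } else if (is.matrix(es)) es
  else stop("expected an entropy_set or a subjects x edges matrix")
}

#' Proportional threshold template
#'
#' Keeps the `floor(density * E)` edges with the largest (tail = "HEN") or
#' smallest (tail = "LEN") group-mean ESE, where E is the total edge count.
#' Ties at the cutoff are broken by canonical edge order. Undefined edges
#' never enter a template.
#'
#' @param mean_ese vector from [group_mean_entropy]
#' @param density fraction of all edges to keep, in (0, 1]
#' @param tail "HEN" (high-entropy) or "LEN" (low-entropy)
#' @return object of class `template_mask` with fields `tail`, `density`,
#'   `edges` (canonical edge positions, sorted)
#' @export
proportional_threshold <- function(mean_ese, density, tail = c("HEN", "LEN")) {
  tail <- match.arg(tail)
  stopifnot(density > 0, density <= 1)
  e_total <- length(mean_ese)
  k <- floor(density * e_total)
  if (k < 1) stop("density yields an empty template")
  ok <- which(!is.na(mean_ese))
  if (length(ok) < k) stop("not enough defined edges for the requested density")
  ord <- if (tail == "HEN") order(-mean_ese[ok], ok) else order(mean_ese[ok], ok)
  edges <- sort(ok[ord[seq_len(k)]])
  structure(list(tail = tail, density = density, edges = edges,
                 n_total = e_total), class = "template_mask")
}

#' @export
print.template_mask <- function(x, ...) {
  cat(sprintf("template_mask: %s, density %.4f, %d / %d edges\n",
              x$tail, x$density, length(x$edges), x$n_total))
  invisible(x)
}

#' Inter-subject similarity of masked entropy vectors
#'
#' Extracts the template's edges from each analysis subject's ESE vector
#' and correlates subjects pairwise (Pearson). Undefined values trigger
#' pairwise-complete correlation with a message. The diagonal is set to 1.
#'
#' @param es an `entropy_set` or subjects x edges matrix (the patients in
#'   the study design)
#' @param mask a [template_mask]
#' @param group subjects to use when `es` is an `entropy_set`
#' @return object of class `similarity_matrix`: `R` (N x N), subject ids,
#'   and the source mask
#' @export
build_similarity <- function(es, mask, group = "patient") {
  stopifnot(inherits(mask, "template_mask"))
  m <- entropy_matrix(es, group)
  if (nrow(m) < 3) stop("need at least 3 subjects for a similarity matrix")
  z <- m[, mask$edges, drop = FALSE]
  sds <- apply(z, 1, function(r) sd_pop(r[!is.na(r)]))
  if (any(sds == 0))
    stop(sprintf("zero-variance masked entropy vector for subject %s",
                 rownames(z)[which(sds == 0)[1]]))
  use <- "everything"
  if (anyNA(z)) {
    message("undefined entropy values inside the mask; using pairwise-complete correlation")
    use <- "pairwise.complete.obs"
  }
  R <- cor(t(z), use = use)
  diag(R) <- 1
  structure(list(R = R, subject_ids = rownames(z), mask = mask),
            class = "similarity_matrix")
}

#' Template density sweep and selection
#'
#' Builds HEN and LEN templates over a grid of candidate densities,
#' extracts patient similarity matrices, fits the variance-component model
#' for each candidate, and ranks candidates within each tail on four
#' criteria: mean variance explained across measures (higher better),
#' Wald p (lower better), permutation p (lower better), and concordance
#' |p-Perm - p-Wald| (smaller better). The winner per tail has the best
#' (highest) average rank; rank ties are broken toward the lower density.
#'
#' @param mean_ese template-group mean ESE from [group_mean_entropy]
#' @param es an `entropy_set` (or matrix) providing the analysis group
#' @param Y N x P behavioral matrix (quantile-normalized), rows aligned to
#'   the analysis subjects
#' @param X N x q covariate matrix (an intercept is appended internally)
#' @param densities candidate density grid (default 1%..16% in 1% steps,
#'   16 candidates per tail -> 32 templates)
#' @param n_perm permutations per candidate for p-Perm (default 1000)
#' @param seed RNG seed for the permutation tests
#' @param group analysis group when `es` is an `entropy_set`
#' @return list with `ranking` (one row per candidate: tail, density,
#'   mean_var_explained, p_wald, p_perm, concordance, rank_* columns,
#'   avg_rank, selected), and `selected`, a list with the winning
#'   [template_mask] and [build_similarity] output per tail
#' @export
sweep_templates <- function(mean_ese, es, Y, X = NULL,
                            densities = (1:16) / 100,
                            n_perm = 1000L, seed = 1L, group = "patient") {
  stopifnot(all(diff(densities) > 0), length(densities) >= 1)
  rows <- list(); masks <- list()
  for (tail in c("HEN", "LEN")) {
    for (d in densities) {
      key <- sprintf("%s_%g", tail, d)
      rec <- tryCatch({
        mask <- proportional_threshold(mean_ese, d, tail)
        sim <- build_similarity(es, mask, group = group)
        pr <- project_out_covariates(Y, X, sim$R)
        fit <- fit_varcomp(pr$Y, pr$R)
        pp <- permutation_p(pr$Y, pr$R, n_perm = n_perm,
                            seed = derive_seed(seed, length(rows)))
        masks[[key]] <- list(mask = mask, sim = sim, fit = fit)
        data.frame(tail = tail, density = d,
                   mean_var_explained = mean(fit$M_i),
                   p_wald = fit$p_wald, p_perm = pp,
                   concordance = abs(pp - fit$p_wald),
                   failed = FALSE)
      }, error = function(e) {
        message(sprintf("candidate %s failed: %s", key, conditionMessage(e)))
        data.frame(tail = tail, density = d, mean_var_explained = NA,
                   p_wald = NA, p_perm = NA, concordance = NA, failed = TRUE)
      })
      rows[[key]] <- rec
    }
  }
  ranking <- do.call(rbind, rows)
  rownames(ranking) <- NULL
  ranking$rank_var <- NA; ranking$rank_wald <- NA
  ranking$rank_perm <- NA; ranking$rank_conc <- NA
  ranking$avg_rank <- NA; ranking$selected <- FALSE
  selected <- list()
  for (tail in c("HEN", "LEN")) {
    idx <- which(ranking$tail == tail & !ranking$failed)
    if (!length(idx)) next
    # higher rank number = better on each criterion
    ranking$rank_var[idx]  <- rank(ranking$mean_var_explained[idx], ties.method = "average")
    ranking$rank_wald[idx] <- rank(-ranking$p_wald[idx], ties.method = "average")
    ranking$rank_perm[idx] <- rank(-ranking$p_perm[idx], ties.method = "average")
    ranking$rank_conc[idx] <- rank(-ranking$concordance[idx], ties.method = "average")
    ranking$avg_rank[idx] <- rowMeans(ranking[idx, c("rank_var", "rank_wald",
                                                     "rank_perm", "rank_conc")])
    best <- idx[order(-ranking$avg_rank[idx], ranking$density[idx])][1]
    ranking$selected[best] <- TRUE
    key <- sprintf("%s_%g", tail, ranking$density[best])
    selected[[tail]] <- masks[[key]]
  }
  list(ranking = ranking, selected = selected)
}
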