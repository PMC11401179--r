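#' Eight-system parcel labels
#'
#' The canonical system set: seven cortical resting-state networks plus
#' subcortex.
#' @export
SYSTEM_LABELS <- c("VIS", "SM", "DAT", "SAL", "LIM", "CC", "DMN", "SC")

# block id for an unordered pair of system indices (1..8) -> 1..36
block_id <- function(a, b, k = 8L) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  (lo - 1L) * k - lo * (lo - 1L) / 2L + hi - lo + 1L
}

block_names <- function(labels = SYSTEM_LABELS) {
  k <- length(labels)
  out <- character(k * (k + 1L) / 2L)
  for (a in seq_len(k)) for (b in a:k)
    out[block_id(a, b, k)] <- paste(labels[a], labels[b], sep = "-")
  out
}

# system index per edge of the full canonical edge set
edge_blocks <- function(labels, n_parcels) {
  stopifnot(length(labels) == n_parcels)
  li <- match(labels, SYSTEM_LABELS)
  if (anyNA(li)) stop("labels must be one of: ", paste(SYSTEM_LABELS, collapse = ", "))
  ei <- edge_index(n_parcels)
  block_id(li[ei$i], li[ei$j])
}

#' System-block averages of edge values
#'
#' Averages edgewise values within and between the 8 systems (7 cortical
#' networks + subcortex), over the edges of a template mask.
#'
#' @param edge_values numeric vector of values for the mask's edges (same
#'   order as `mask$edges`)
#' @param mask a [template_mask]
#' @param labels system label per parcel (values in [SYSTEM_LABELS])
#' @return object of class `system_blocks`: 8 x 8 symmetric matrices
#'   `mean` and `count` (block edge counts); empty blocks are NA
#' @export
block_average <- function(edge_values, mask, labels) {
  stopifnot(inherits(mask, "template_mask"), length(edge_values) == length(mask$edges))
  n_parcels <- (1 + sqrt(1 + 8 * mask$n_total)) / 2
  bid <- edge_blocks(labels, n_parcels)[mask$edges]
  nb <- length(SYSTEM_LABELS) * (length(SYSTEM_LABELS) + 1L) / 2L
  keep <- !is.na(edge_values)
  sums <- rowsum(edge_values[keep], bid[keep])
  cnt <- tabulate(bid[keep], nb)
  mu <- rep(NA_real_, nb)
  mu[as.integer(rownames(sums))] <- sums[, 1] / cnt[as.integer(rownames(sums))]
  to_mat <- function(v) {
    k <- length(SYSTEM_LABELS)
    m <- matrix(NA_real_, k, k, dimnames = list(SYSTEM_LABELS, SYSTEM_LABELS))
    for (a in seq_len(k)) for (b in a:k) m[a, b] <- m[b, a] <- v[block_id(a, b)]
    m
  }
  structure(list(mean = to_mat(mu), count = to_mat(cnt),
                 block_mean = setNames(mu, block_names()),
                 block_count = setNames(cnt, block_names())),
            class = "system_blocks")
}

#' Edge-shuffle null for system-block statistics
#'
#' Relocates the template's edges uniformly among all possible parcel
#' pairs (size- and density-matched), carrying their values, and
#' recomputes block means per permutation. One-sided "greater" p-values
#' use the add-one estimator (1 + #\{null >= empirical\}) / (n_perm + 1),
#' so p is never zero.
#'
#' @inheritParams block_average
#' @param n_perm permutations (>= 100; study analyses used 10,000)
#' @param seed RNG seed
#' @param relocate if FALSE, permute values over the fixed mask instead of
#'   relocating edges (the alternative reading of "shuffling edges"; both
#'   preserve size and density)
#' @return list with `observed` ([block_average] result), `p` (named
#'   vector per block, NA where the block is empty), `n_perm`, `model`
#' @export
null_edge_shuffle <- function(edge_values, mask, labels, n_perm = 10000L,
                              seed = 1L, relocate = TRUE) {
  stopifnot(n_perm >= 100)
  obs <- block_average(edge_values, mask, labels)
  n_parcels <- (1 + sqrt(1 + 8 * mask$n_total)) / 2
  bid_all <- edge_blocks(labels, n_parcels)
  nb <- length(obs$block_mean)
  k <- length(mask$edges)
  keep <- !is.na(edge_values)
  vals <- edge_values[keep]
  set.seed(seed)
  ge <- integer(nb)
  for (b in seq_len(n_perm)) {
    bid <- if (relocate) bid_all[sample.int(mask$n_total, k)][keep]
           else bid_all[mask$edges][sample.int(k)][keep]
    sums <- rowsum(vals, bid)
    cnt <- tabulate(bid, nb)
    mu <- rep(NA_real_, nb)
    ridx <- as.integer(rownames(sums))
    mu[ridx] <- sums[, 1] / cnt[ridx]
    ge <- ge + (!is.na(mu) & !is.na(obs$block_mean) & mu >= obs$block_mean)
  }
  p <- (1 + ge) / (n_perm + 1)
  p[is.na(obs$block_mean)] <- NA_real_
  list(observed = obs, p = setNames(p, names(obs$block_mean)),
       n_perm = n_perm, model = if (relocate) "edge-shuffle" else "value-permute")
}

#' Degree/strength-preserving rewiring null
#'
#' Rewires the binary mask graph with degree-preserving double-edge swaps,
#' then reassigns the original edge values greedily so that edges whose
#' endpoints had the highest original nodal strength receive the largest
#' values (approximate strength matching). Block means are recomputed per
#' permutation; one-sided "greater" p-values with the add-one rule.
#'
#' @inheritParams null_edge_shuffle
#' @return list with `observed`, `p`, `n_perm`, `model`, and
#'   `strength_spearman` (per-permutation Spearman correlation between
#'   original and rewired nodal strengths)
#' @export
null_rewire <- function(edge_values, mask, labels, n_perm = 10000L, seed = 1L) {
  stopifnot(n_perm >= 100)
  obs <- block_average(edge_values, mask, labels)
  n_parcels <- as.integer((1 + sqrt(1 + 8 * mask$n_total)) / 2)
  ei <- edge_index(n_parcels)
  epairs <- cbind(ei$i[mask$edges], ei$j[mask$edges])
  k <- nrow(epairs)
  # rewirable only if two vertex-disjoint edges exist
  disjoint <- FALSE
  for (a in seq_len(min(k - 1, 200))) {
    if (any(!(epairs[(a + 1):k, 1] %in% epairs[a, ]) &
            !(epairs[(a + 1):k, 2] %in% epairs[a, ]))) { disjoint <- TRUE; break }
  }
  if (!disjoint) stop("mask graph too constrained to rewire (no vertex-disjoint edge pairs)")
  li <- match(labels, SYSTEM_LABELS)
  keep <- !is.na(edge_values)
  w_sorted <- sort(edge_values[keep], decreasing = TRUE)
  strength <- rep(0, n_parcels)
  for (r in which(keep)) {
    strength[epairs[r, 1]] <- strength[epairs[r, 1]] + edge_values[r]
    strength[epairs[r, 2]] <- strength[epairs[r, 2]] + edge_values[r]
  }
  g0 <- igraph::graph_from_edgelist(epairs, directed = FALSE)
  if (igraph::vcount(g0) < n_parcels)
    g0 <- igraph::add_vertices(g0, n_parcels - igraph::vcount(g0))
  nb <- length(obs$block_mean)
  set.seed(seed)
  ge <- integer(nb)
  sp <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    g <- igraph::rewire(g0, igraph::keeping_degseq(niter = 10 * k))
    el <- igraph::as_edgelist(g, names = FALSE)
    score <- strength[el[, 1]] + strength[el[, 2]]
    ord <- order(-score)
    w <- numeric(k)
    w[ord] <- c(w_sorted, rep(NA_real_, k - length(w_sorted)))
    kp <- !is.na(w)
    s2 <- rep(0, n_parcels)
    for (r in which(kp)) {
      s2[el[r, 1]] <- s2[el[r, 1]] + w[r]
      s2[el[r, 2]] <- s2[el[r, 2]] + w[r]
    }
    sp[b] <- suppressWarnings(cor(strength, s2, method = "spearman"))
    bid <- block_id(li[el[kp, 1]], li[el[kp, 2]])
    sums <- rowsum(w[kp], bid)
    cnt <- tabulate(bid, nb)
    mu <- rep(NA_real_, nb)
    ridx <- as.integer(rownames(sums))
    mu[ridx] <- sums[, 1] / cnt[ridx]
    ge <- ge + (!is.na(mu) & !is.na(obs$block_mean) & mu >= obs$block_mean)
  }
  p <- (1 + ge) / (n_perm + 1)
  p[is.na(obs$block_mean)] <- NA_real_
  list(observed = obs, p = setNames(p, names(obs$block_mean)),
       n_perm = n_perm, model = "degree-strength-rewire",
       strength_spearman = sp)
}

#' Benjamini-Hochberg significance mask
#'
#' Step-up FDR control at level q; NA p-values are excluded from the
#' family and returned as NA.
#'
#' @param pvals p-values in [0, 1] (NA allowed)
#' @param q FDR level (default 0.05)
#' @return logical vector, TRUE where significant
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  out <- rep(NA, length(pvals))
  ok <- !is.na(pvals)
  stopifnot(all(pvals[ok] >= 0 & pvals[ok] <= 1))
  out[ok] <- p.adjust(pvals[ok], method = "BH") <= q
  out
}

#' Normalized degree-centrality under a density-matched null
#'
#' Binary degree of every parcel in the template, normalized by the mean
#' degree over uniform relocations of the same number of edges
#' (size- and density-matched random networks), with a one-sided
#' "greater" p-value per node.
#'
#' @param mask a [template_mask]
#' @param n_perm permutations (study analyses used 10,000)
#' @param seed RNG seed
#' @return data.frame: `parcel`, `degree`, `null_mean`, `normalized`, `p`
#' @export
degree_centrality <- function(mask, n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(mask, "template_mask"))
  n_parcels <- as.integer((1 + sqrt(1 + 8 * mask$n_total)) / 2)
  ei <- edge_index(n_parcels)
  deg <- tabulate(c(ei$i[mask$edges], ei$j[mask$edges]), n_parcels)
  k <- length(mask$edges)
  set.seed(seed)
  sum_deg <- numeric(n_parcels)
  ge <- integer(n_parcels)
  for (b in seq_len(n_perm)) {
    e <- sample.int(mask$n_total, k)
    d <- tabulate(c(ei$i[e], ei$j[e]), n_parcels)
    sum_deg <- sum_deg + d
    ge <- ge + (d >= deg)
  }
  null_mean <- sum_deg / n_perm
  data.frame(parcel = seq_len(n_parcels), degree = deg,
             null_mean = null_mean, normalized = deg / null_mean,
             p = (1 + ge) / (n_perm + 1))
}

#' Node-entropy topography
#'
#' Difference of normalized HEN and LEN degree-centralities on cortical
#' parcels (HEN - LEN), min-max rescaled to [0, 1]. High values mark
#' parcels central in the high-entropy configuration, low values parcels
#' central in the low-entropy configuration.
#'
#' @param cent_hen,cent_len data.frames from [degree_centrality] on the
#'   same parcels
#' @param cortical_ids parcel indices of the cortical parcels
#' @return named numeric vector in [0, 1], one value per cortical parcel
#' @export
node_entropy <- function(cent_hen, cent_len, cortical_ids) {
  stopifnot(identical(cent_hen$parcel, cent_len$parcel))
  d <- (cent_hen$normalized - cent_len$normalized)[match(cortical_ids, cent_hen$parcel)]
  if (anyNA(d)) stop("cortical ids missing from the centrality tables")
  rng <- range(d)
  if (rng[1] == rng[2])
    stop("degenerate node-entropy: HEN and LEN centralities are identical up to a constant")
  setNames((d - rng[1]) / (rng[2] - rng[1]), cortical_ids)
}
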