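#' Binned spatial variogram
#'
#' Empirical semivariogram gamma(h) = mean of 0.5 (x_i - x_j)^2 over
#' parcel pairs whose distance falls in each bin. Bins are equal-count
#' quantile bins of the pairwise distances up to `max_frac` of the
#' maximum distance.
#'
#' @param x parcel values
#' @param D pairwise distance matrix
#' @param n_bins number of distance bins (default 15)
#' @param max_frac fraction of the maximum distance to include (default
#'   0.75; long-range pairs are sparse and noisy)
#' @return data.frame with `h` (bin center) and `gamma`
#' @export
spatial_variogram <- function(x, D, n_bins = 15L, max_frac = 0.75) {
  lt <- lower.tri(D)
  d <- D[lt]
  sq <- 0.5 * (outer(x, x, "-")[lt])^2
  keep <- d <= max_frac * max(d)
  d <- d[keep]; sq <- sq[keep]
  br <- unique(quantile(d, seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(d, br, include.lowest = TRUE)
  data.frame(h = tapply(d, bin, mean), gamma = tapply(sq, bin, mean))
}

#' Variogram-matched surrogate maps
#'
#' Generates surrogate maps that preserve the value distribution exactly
#' (rank remapping onto the source values) while approximately matching
#' the source map's spatial variogram: each surrogate starts from a random
#' permutation, is smoothed by distance-decaying kernels over a grid of
#' bandwidths; per bandwidth, the smooth field and the white permutation
#' are blended with nonnegative least-squares weights fitted to the
#' source variogram (variograms of independent fields add), the blend is
#' rank-remapped to the source values, and the candidate with the
#' smallest relative squared variogram mismatch is kept.
#'
#' @param x source map, one value per parcel
#' @param coords parcel coordinates (n x d matrix) or a precomputed
#'   distance matrix
#' @param n number of surrogates
#' @param seed RNG seed
#' @param bandwidths kernel bandwidths as fractions of the maximum
#'   distance
#' @param n_bins variogram bins
#' @return matrix of surrogates (n_parcels x n)
#' @export
variogram_surrogates <- function(x, coords, n = 1000L, seed = 1L,
                                 bandwidths = c(0.02, 0.04, 0.07, 0.12, 0.2, 0.35, 0.55, 0.8),
                                 n_bins = 15L) {
  np <- length(x)
  if (np < 20) stop("need at least 20 parcels for surrogate generation")
  if (sd(x) == 0) stop("all-equal map cannot be surrogated")
  D <- if (is.matrix(coords) && nrow(coords) == ncol(coords) &&
           isTRUE(all.equal(coords, t(coords)))) coords
       else as.matrix(dist(coords))
  lt <- lower.tri(D)
  dvec <- D[lt]
  keep <- dvec <= 0.75 * max(dvec)
  br <- unique(quantile(dvec[keep], seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(dvec[keep], br, include.lowest = TRUE)
  vg <- function(v) {
    sq <- 0.5 * (outer(v, v, "-")[lt])[keep]^2
    as.numeric(tapply(sq, bin, mean))
  }
  vg_src <- vg(x)
  xs <- sort(x)
  # smoothing kernels, rows normalized; self-weight included
  Ws <- lapply(bandwidths, function(b) {
    W <- exp(-D / (b * max(D)))
    W / rowSums(W)
  })
  set.seed(seed)
  zs <- function(v) (v - mean(v)) / sd(v)
  out <- matrix(NA_real_, np, n)
  for (s in seq_len(n)) {
    perm <- sample(x)
    zperm <- zs(perm)
    vg_p <- vg(zperm)
    best <- perm; best_err <- sum(((vg(perm) - vg_src) / vg_src)^2)
    for (W in Ws) {
      sm <- zs(as.numeric(W %*% perm))
      vg_s <- vg(sm)
      # variograms of independent fields add: gamma(a*sm + b*noise) ~
      # a^2 gamma_sm + b^2 gamma_noise; solve the weighted least-squares
      # mixture (clamped at 0) against the source variogram
      A <- cbind(vg_s, vg_p) / vg_src
      ab <- tryCatch(qr.solve(crossprod(A), crossprod(A, vg_src / vg_src)),
                     error = function(e) c(1, 0))
      ab <- pmax(as.numeric(ab), 0)
      if (sum(ab) == 0) ab <- c(1, 0)
      mix <- sqrt(ab[1]) * sm + sqrt(ab[2]) * zperm
      cand <- xs[rank(mix, ties.method = "first")]
      err <- sum(((vg(cand) - vg_src) / vg_src)^2)
      if (err < best_err) { best <- cand; best_err <- err }
    }
    out[, s] <- best
  }
  out
}

#' Spatially constrained map-correlation tests
#'
#' Pearson correlation between a node-entropy (or any parcel) map and a
#' set of annotation maps. Maps with |r| below `r_min` are dropped before
#' testing (the study retained maps with |r| >= 0.2); for retained maps a
#' two-sided surrogate p-value compares |r| against surrogates of the
#' annotation map that preserve its spatial autocorrelation, and the
#' retained family is BH-FDR corrected.
#'
#' @param node_map named or plain numeric vector over cortical parcels
#' @param maps named list of annotation maps (aligned to `node_map`)
#' @param coords parcel coordinates or distance matrix for surrogate
#'   generation
#' @param r_min retention threshold on |r| (default 0.2)
#' @param n_surr surrogates per map (study analyses used 10,000)
#' @param seed RNG seed
#' @param q FDR level (default 0.05)
#' @return data.frame: `map`, `r`, `retained`, `p` (surrogate, two-sided),
#'   `p_fdr`, `significant`
#' @export
map_correlation_test <- function(node_map, maps, coords, r_min = 0.2,
                                 n_surr = 1000L, seed = 1L, q = 0.05) {
  stopifnot(is.list(maps), length(maps) >= 1)
  np <- length(node_map)
  bad <- names(maps)[vapply(maps, length, 1L) != np]
  if (length(bad))
    stop("maps not aligned to the node map: ", paste(bad, collapse = ", "))
  r <- vapply(maps, function(m) cor(node_map, m), numeric(1))
  retained <- abs(r) >= r_min
  p <- rep(NA_real_, length(maps))
  for (k in which(retained)) {
    surr <- variogram_surrogates(maps[[k]], coords, n = n_surr,
                                 seed = derive_seed(seed, k))
    r_surr <- as.numeric(cor(node_map, surr))
    p[k] <- (1 + sum(abs(r_surr) >= abs(r[k]))) / (n_surr + 1)
  }
  p_fdr <- rep(NA_real_, length(maps))
  p_fdr[retained] <- p.adjust(p[retained], method = "BH")
  data.frame(map = if (is.null(names(maps))) seq_along(maps) else names(maps),
             r = r, retained = retained, p = p, p_fdr = p_fdr,
             significant = !is.na(p_fdr) & p_fdr <= q,
             row.names = NULL)
}

#' Confound-map correlation check
#'
#' Correlates centrality-derived maps (e.g. node-entropy, HEN and LEN
#' normalized degree) with a single control map (such as a temporal
#' signal-to-noise map) and reports plain Pearson r with an uncorrected
#' two-sided surrogate p per map.
#'
#' @param centrality_maps named list of parcel maps
#' @param control_map the confound map, aligned to the centrality maps
#' @param coords coordinates or distance matrix
#' @param n_surr surrogates (default 1000)
#' @param seed RNG seed
#' @return data.frame: `map`, `r`, `p` (uncorrected)
#' @export
control_map_correlation <- function(centrality_maps, control_map, coords,
                                    n_surr = 1000L, seed = 1L) {
  stopifnot(is.list(centrality_maps))
  surr <- variogram_surrogates(control_map, coords, n = n_surr, seed = seed)
  rows <- lapply(seq_along(centrality_maps), function(k) {
    v <- centrality_maps[[k]]
    stopifnot(length(v) == length(control_map))
    r <- cor(v, control_map)
    r_surr <- as.numeric(cor(v, surr))
    data.frame(map = names(centrality_maps)[k], r = r,
               p = (1 + sum(abs(r_surr) >= abs(r))) / (n_surr + 1))
  })
  do.call(rbind, rows)
}
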