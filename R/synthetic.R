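#' Synthetic study configuration
#'
#' Dimensions and acquisition parameters of a simulated study. Defaults
#' mirror the reference design: 97 patients and 53 controls, 116 parcels,
#' 410 frames at TR 0.8 s (so that 10+10 trimmed frames and a 75-frame
#' window yield 316 sliding windows), 7 behavioral measures and 5
#' covariates.
#'
#' @param n_controls,n_patients group sizes
#' @param n_parcels number of parcels
#' @param n_frames frames per run
#' @param tr repetition time, seconds
#' @param n_measures behavioral measures
#' @param n_covariates covariates
#' @param seed integer seed recorded in all generated artifacts
#' @return list with class `sim_config`
#' @export
sim_config <- function(n_controls = 53L, n_patients = 97L, n_parcels = 116L,
                       n_frames = 410L, tr = 0.8, n_measures = 7L,
                       n_covariates = 5L, seed = 1L) {
  cfg <- list(n_controls = as.integer(n_controls),
              n_patients = as.integer(n_patients),
              n_parcels = as.integer(n_parcels),
              n_frames = as.integer(n_frames), tr = tr,
              n_measures = as.integer(n_measures),
              n_covariates = as.integer(n_covariates),
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_controls", "n_patients", "n_parcels", "n_frames",
                         "n_measures", "n_covariates")])
  if (any(counts < 2)) stop("all counts must be >= 2")
  if (tr <= 0) stop("tr must be positive")
  structure(cfg, class = "sim_config")
}

#' Edge regularity plan
#'
#' Declares the planted structure of the simulated edge dynamics.
#' "Regular" edges are vertex-disjoint parcel pairs whose coupling is
#' modulated by a slow sinusoidal mixing weight (period
#' `regular_timescale` frames): their windowed correlation drifts smoothly
#' and has low sample entropy. "Irregular" edges are all edges incident to
#' a small set of fast hub parcels whose signals live at the top of the
#' analysis passband (carrier period `irregular_timescale` frames); the
#' spectral mismatch between a fast hub and a mid-band partner puts the
#' correlation-product energy at high frequencies, so these edges have
#' rough dynamics and high sample entropy. Background parcels carry
#' independent mid-band noise, landing between the two planted classes.
#'
#' @param regular_edges canonical edge positions of the slow-coupled pairs
#' @param fast_hubs parcel indices of the fast hub nodes (>= 1; >= 2 makes
#'   the irregular template rewirable)
#' @param n_parcels total parcel count (needed to enumerate hub edges)
#' @param regular_timescale slow modulation period, frames (default 700)
#' @param irregular_timescale fast carrier period, frames (default 12.5,
#'   i.e. 10 s at TR 0.8 s, the fast edge of the 0.017-0.1 Hz band)
#' @param amplitude peak coupling strength of regular edges in (0, 1)
#'   (default 0.95)
#' @return list with class `edge_plan`; `irregular_edges` holds the
#'   canonical positions of all hub x non-hub edges
#' @export
edge_plan <- function(regular_edges, fast_hubs, n_parcels,
                      regular_timescale = 700, irregular_timescale = 12.5,
                      amplitude = 0.95) {
  if (regular_timescale < 2 || irregular_timescale < 2)
    stop("invalid plan: timescale shorter than 2 frames")
  if (regular_timescale <= irregular_timescale)
    stop("regular_timescale must exceed irregular_timescale")
  stopifnot(amplitude > 0, amplitude < 1, length(fast_hubs) >= 1)
  ei <- edge_index(n_parcels)
  irregular <- which((ei$i %in% fast_hubs) != (ei$j %in% fast_hubs))
  reg_nodes <- c(ei$i[regular_edges], ei$j[regular_edges])
  if (anyDuplicated(reg_nodes))
    stop("regular edges must be vertex-disjoint")
  if (any(reg_nodes %in% fast_hubs))
    stop("regular edges may not touch fast hubs")
  if (length(intersect(regular_edges, irregular)))
    stop("regular and irregular edge sets must be disjoint")
  structure(list(regular_edges = as.integer(sort(regular_edges)),
                 irregular_edges = as.integer(irregular),
                 fast_hubs = as.integer(sort(fast_hubs)),
                 n_parcels = as.integer(n_parcels),
                 regular_timescale = regular_timescale,
                 irregular_timescale = irregular_timescale,
                 amplitude = amplitude),
            class = "edge_plan")
}

#' Default edge plan
#'
#' `n_regular` slow-coupled pairs on the first parcels (1-2, 3-4, ...)
#' and `n_fast_hubs` fast hubs on the last parcels.
#'
#' @param n_parcels parcel count
#' @param n_regular number of regular (slow) pairs
#' @param n_fast_hubs number of fast hub parcels (default 2)
#' @param ... further arguments to [edge_plan]
#' @return an `edge_plan`
#' @export
default_edge_plan <- function(n_parcels, n_regular = 10L, n_fast_hubs = 2L, ...) {
  if (2L * n_regular + n_fast_hubs > n_parcels)
    stop("not enough parcels for the requested plan")
  nodes <- matrix(seq_len(2L * n_regular), ncol = 2, byrow = TRUE)
  edge_plan(regular_edges = edge_position(nodes[, 1], nodes[, 2], n_parcels),
            fast_hubs = n_parcels - seq_len(n_fast_hubs) + 1L,
            n_parcels = n_parcels, ...)
}

# band-limited unit-variance noise (the passband of the analysis pipeline,
# so preprocessing is close to the identity on generated signals)
bandlimited_noise <- function(n_frames, n_signals, tr, band = c(0.017, 0.1)) {
  nyq <- 1 / (2 * tr)
  bf <- signal::butter(4, band / nyq, type = "pass")
  pad <- 100L
  x <- matrix(rnorm((n_frames + 2 * pad) * n_signals), ncol = n_signals)
  x <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  x <- x[(pad + 1):(pad + n_frames), , drop = FALSE]
  scale(x)[, , drop = FALSE]
}

#' Simulate parcel timeseries with planted edge dynamics
#'
#' Background parcels carry independent band-limited noise in a mid
#' sub-band of the analysis passband (`base_band`, default 0.03-0.08 Hz).
#' For each regular edge (p, q), node q is rebuilt as
#' `w(t) x_p + sqrt(1 - w(t)^2) x_q` with a slow sinusoidal mixing weight
#' `w(t) = amplitude * sin(2 pi t / T_reg + phase)` (random phase per
#' subject and edge), so the pair's windowed correlation tracks a smooth
#' large-amplitude trajectory. Fast hub parcels are replaced by
#' band-limited noise whose carrier period is `irregular_timescale`
#' frames (a narrow band at the top of the passband); the correlation of
#' a hub with any other parcel fluctuates roughly at the window scale.
#' All columns are standardized to zero mean, unit variance before
#' export. Every signal lies inside the analysis passband, so the
#' preprocessing stage is close to the identity on generated data.
#'
#' @param cfg a [sim_config]
#' @param plan an [edge_plan]; NULL plants nothing
#' @param base_band background sub-band in Hz
#' @return a [parcel_ts_set] (controls first, then patients)
#' @export
simulate_timeseries <- function(cfg, plan = NULL, base_band = c(0.03, 0.08)) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$n_parcels
  ei <- edge_index(p)
  if (!is.null(plan)) {
    stopifnot(inherits(plan, "edge_plan"))
    if (plan$n_parcels != p) stop("plan was built for a different parcel count")
  }
  n_sub <- cfg$n_controls + cfg$n_patients
  set.seed(cfg$seed)
  subjects <- vector("list", n_sub)
  tgrid <- seq_len(cfg$n_frames)
  if (!is.null(plan)) {
    f_c <- 1 / (plan$irregular_timescale * cfg$tr)
    fast_band <- c(f_c / 1.18, f_c)
    if (f_c >= 1 / (2 * cfg$tr))
      stop("irregular carrier exceeds the Nyquist frequency")
  }
  for (s in seq_len(n_sub)) {
    x <- bandlimited_noise(cfg$n_frames, p, cfg$tr, band = base_band)
    if (!is.null(plan)) {
      for (e in plan$regular_edges) {
        i <- ei$i[e]; j <- ei$j[e]
        w <- plan$amplitude *
          sin(2 * pi * tgrid / plan$regular_timescale + runif(1, 0, 2 * pi))
        x[, j] <- w * x[, i] + sqrt(1 - w^2) * x[, j]
      }
      x[, plan$fast_hubs] <- bandlimited_noise(cfg$n_frames,
                                               length(plan$fast_hubs),
                                               cfg$tr, band = fast_band)
    }
    subjects[[s]] <- scale(x)[, , drop = FALSE]
  }
  names(subjects) <- sprintf("sub%03d", seq_len(n_sub))
  parcel_ts_set(subjects, tr = cfg$tr,
                group = rep(c("control", "patient"),
                            c(cfg$n_controls, cfg$n_patients)))
}

#' Simulate the covariate table
#'
#' Emulates the distributional shape of the study covariates: age (normal,
#' mean 22.65, sd 3.36 years), sex (Bernoulli 0.37), antipsychotic dose in
#' chlorpromazine equivalents (half-normal, mean ~175 mg), mean framewise
#' displacement (lognormal, mean ~0.12 mm), and phenotype (Bernoulli,
#' affective fraction 24/97).
#'
#' @param n subjects
#' @param seed RNG seed
#' @return data.frame with columns age, sex, medication, fd, phenotype
#' @export
simulate_covariates <- function(n, seed = 1L) {
  set.seed(seed)
  data.frame(age = rnorm(n, 22.65, 3.36),
             sex = rbinom(n, 1, 0.37),
             medication = abs(rnorm(n, 0, 175.52 * sqrt(pi / 2))),
             fd = rlnorm(n, log(0.12) - 0.223 / 2, sqrt(0.223)),
             phenotype = rbinom(n, 1, 24 / 97))
}

# symmetric PSD square root; errors on clearly negative eigenvalues
psd_sqrt <- function(S, name = "matrix", tol = 1e-8) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lmin <- min(e$values)
  if (lmin < -tol * max(abs(e$values), 1))
    stop(sprintf("%s is not positive semi-definite (eigenvalue %.3g)", name, lmin))
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate behavioral scores from the variance-component model
#'
#' Draws Y = XB + sum_k C_k + E, where each structured component C_k has
#' Vec(C_k) ~ N(0, Sigma_k (x) R_k) (built as L_R Z L_S' with L L' the
#' PSD square roots) and E has i.i.d. rows N(0, Sigma_e). Supplying one
#' component reproduces the single-kernel generative model; two components
#' with different kernels plant a HEN/LEN contrast.
#'
#' @param X N x q covariate matrix or NULL
#' @param B q x P fixed-effect matrix (ignored when X is NULL)
#' @param components list of `list(Sigma = P x P PSD, R = N x N PSD)`
#' @param Sigma_e P x P positive-definite residual covariance
#' @param seed RNG seed
#' @return N x P matrix of scores
#' @export
simulate_behavior <- function(X, B, components, Sigma_e, seed = 1L) {
  stopifnot(is.list(components))
  P <- nrow(Sigma_e)
  n <- if (!is.null(X)) nrow(as.matrix(X)) else nrow(components[[1]]$R)
  set.seed(seed)
  Y <- matrix(0, n, P)
  if (!is.null(X)) {
    X <- as.matrix(X)
    stopifnot(nrow(B) == ncol(X), ncol(B) == P)
    Y <- Y + X %*% B
  }
  for (k in seq_along(components)) {
    comp <- components[[k]]
    stopifnot(nrow(comp$R) == n, nrow(comp$Sigma) == P)
    LR <- psd_sqrt(comp$R, sprintf("similarity kernel R[%d]", k))
    LS <- psd_sqrt(comp$Sigma, sprintf("Sigma_c[%d]", k))
    Y <- Y + LR %*% matrix(rnorm(n * P), n, P) %*% t(LS)
  }
  if (min(eigen(Sigma_e, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("Sigma_e must be positive definite")
  Le <- psd_sqrt(Sigma_e, "Sigma_e")
  Y <- Y + matrix(rnorm(n * P), n, P) %*% t(Le)
  colnames(Y) <- sprintf("m%d", seq_len(P))
  Y
}

#' Covariance components for a planted variance fraction
#'
#' Convenience constructor: isotropic Sigma_c = f * I and
#' Sigma_e = (1 - sum f) * I so that the planted overall (and per-measure)
#' variance fraction of component k is `fractions[k]`.
#'
#' @param fractions planted fraction per kernel (sum < 1)
#' @param kernels list of N x N PSD similarity kernels, one per fraction
#' @param n_measures P
#' @return list with `components` and `Sigma_e`, ready for
#'   [simulate_behavior]
#' @export
planted_behavior_spec <- function(fractions, kernels, n_measures = 7L) {
  stopifnot(length(fractions) == length(kernels), sum(fractions) < 1,
            all(fractions >= 0))
  comps <- lapply(seq_along(fractions), function(k)
    list(Sigma = diag(fractions[k], n_measures), R = kernels[[k]]))
  list(components = comps,
       Sigma_e = diag(1 - sum(fractions), n_measures))
}

#' Simulate an annotation map with known spatial autocorrelation
#'
#' Gaussian random field with exponential covariance exp(-d / range) on
#' the pairwise Euclidean parcel distances, standardized to zero mean and
#' unit variance.
#'
#' @param coords n x d parcel coordinates (>= 3 distinct rows)
#' @param range_param spatial correlation length (same units as coords)
#' @param seed RNG seed
#' @return numeric vector, one value per parcel
#' @export
simulate_annotation_map <- function(coords, range_param, seed = 1L) {
  if (range_param <= 0) stop("range_param must be positive")
  coords <- as.matrix(coords)
  if (nrow(unique(coords)) < 3) stop("need >= 3 parcels with distinct coordinates")
  D <- as.matrix(dist(coords))
  L <- psd_sqrt(exp(-D / range_param), "spatial covariance")
  set.seed(seed)
  x <- as.numeric(L %*% rnorm(nrow(D)))
  (x - mean(x)) / sd_pop(x)
}

#' Assign 8-system labels to parcels
#'
#' Deterministic labeling: a subcortical block scaled from the reference
#' atlas proportion (16 of 116 parcels), the remainder split as evenly as
#' possible across the seven cortical networks. Every label is non-empty
#' for n_parcels >= 8.
#'
#' @param n_parcels parcel count (>= 8)
#' @return character vector of labels (values in [SYSTEM_LABELS])
#' @export
simulate_network_labels <- function(n_parcels) {
  if (n_parcels < 8) stop("need at least 8 parcels for 8 systems")
  n_sc <- max(1L, round(n_parcels * 16 / 116))
  n_ctx <- n_parcels - n_sc
  if (n_ctx < 7) { n_sc <- n_parcels - 7L; n_ctx <- 7L }
  per <- rep(n_ctx %/% 7L, 7L)
  extra <- n_ctx %% 7L
  if (extra) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  c(rep(SYSTEM_LABELS[1:7], per), rep("SC", n_sc))
}

#' Simulate parcel centroid coordinates
#'
#' One spatial cluster center per system plus isotropic jitter, giving
#' coordinates with system-level spatial structure for annotation-map and
#' surrogate tests.
#'
#' @param labels system labels from [simulate_network_labels]
#' @param seed RNG seed
#' @param spread within-system jitter sd (default 20, arbitrary mm-like
#'   units; centers sit on a ring of radius 50, so systems overlap
#'   spatially and parcels cover the volume semi-uniformly, as cortical
#'   parcel centroids do)
#' @return n x 3 matrix of coordinates
#' @export
simulate_parcel_coords <- function(labels, seed = 1L, spread = 20) {
  set.seed(seed)
  k <- length(SYSTEM_LABELS)
  theta <- 2 * pi * seq_len(k) / k
  centers <- cbind(50 * cos(theta), 50 * sin(theta),
                   30 * cos(2 * theta))
  li <- match(labels, SYSTEM_LABELS)
  centers[li, ] + matrix(rnorm(3 * length(labels), 0, spread), ncol = 3)
}

#' Simulate a complete synthetic study
#'
#' One call producing every pipeline input: labels, coordinates, planted
#' timeseries for controls and patients, and covariates. Behavioral scores
#' are generated downstream once empirical similarity kernels are
#' available (see [simulate_behavior]), closing the loop with the real
#' pipeline.
#'
#' @param cfg a [sim_config]
#' @param plan an [edge_plan] or NULL for a [default_edge_plan]
#' @return list: `cfg`, `plan`, `ts` ([parcel_ts_set]), `covariates`
#'   (patients), `labels`, `coords`
#' @export
simulate_study <- function(cfg = sim_config(), plan = NULL) {
  if (is.null(plan)) plan <- default_edge_plan(cfg$n_parcels)
  ts <- simulate_timeseries(cfg, plan)
  list(cfg = cfg, plan = plan, ts = ts,
       covariates = simulate_covariates(cfg$n_patients,
                                        seed = derive_seed(cfg$seed, 1)),
       labels = simulate_network_labels(cfg$n_parcels),
       coords = simulate_parcel_coords(simulate_network_labels(cfg$n_parcels),
                                       seed = derive_seed(cfg$seed, 2)))
}
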