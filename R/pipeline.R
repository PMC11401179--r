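#' Pipeline run configuration
#'
#' Collects every stage parameter with defaults matching the reference
#' analysis: band 0.017-0.1 Hz, trim 10 frames per end, 60 s rectangular
#' window slid by one TR, SampEn m = 2 and eps = 0.20, candidate densities
#' 1%..16%, FDR level 0.05.
#'
#' @param band bandpass edges in Hz
#' @param trim frames trimmed per end
#' @param window_seconds window width in seconds
#' @param step_frames window step in frames
#' @param m,eps sample entropy parameters
#' @param densities candidate template densities
#' @param n_perm permutations for model-level p-Perm
#' @param n_perm_network permutations for graph nulls
#' @param n_boot bootstrap replicates
#' @param n_surr surrogate maps
#' @param q_fdr FDR level
#' @param alpha contrast family error level
#' @param seed master seed
#' @return list with class `run_config`
#' @export
run_config <- function(band = c(0.017, 0.1), trim = 10L, window_seconds = 60,
                       step_frames = 1L, m = 2L, eps = 0.20,
                       densities = (1:16) / 100, n_perm = 1000L,
                       n_perm_network = 10000L, n_boot = 1000L,
                       n_surr = 1000L, q_fdr = 0.05, alpha = 0.05, seed = 1L) {
  structure(list(band = band, trim = as.integer(trim),
                 window_seconds = window_seconds,
                 step_frames = as.integer(step_frames),
                 m = as.integer(m), eps = eps, densities = densities,
                 n_perm = as.integer(n_perm),
                 n_perm_network = as.integer(n_perm_network),
                 n_boot = as.integer(n_boot), n_surr = as.integer(n_surr),
                 q_fdr = q_fdr, alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full ESE pipeline
#'
#' Executes preprocessing, sliding-window correlation, edgewise sample
#' entropy, the HEN/LEN template sweep with model-based selection, the
#' HEN-vs-LEN bootstrap contrast, edgewise variance with system-block
#' statistics under both graph nulls, normalized degree-centrality and
#' node-entropy, and (when annotation maps are supplied) spatial-surrogate
#' map correlations and the PC1 integration analysis.
#'
#' @param ts a [parcel_ts_set] with control and patient subjects
#' @param behavior N_patients x P behavioral matrix (raw scores; quantile
#'   normalized internally)
#' @param covariates patient covariate matrix/data.frame or NULL
#' @param labels parcel system labels
#' @param config a [run_config]
#' @param coords parcel coordinates (needed for map tests)
#' @param maps optional named list of cortical annotation maps
#' @return list bundle with every stage output and a `manifest`
#' @export
run_full <- function(ts, behavior, covariates = NULL, labels = NULL,
                     config = run_config(), coords = NULL, maps = NULL) {
  stopifnot(inherits(ts, "parcel_ts_set"), inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  pre <- stage("preprocess", preprocess_timeseries(ts, config$band, config$trim))
  ed <- stage("tvfc", sliding_window_correlation(pre, config$window_seconds,
                                                 config$step_frames))
  es <- stage("entropy", edge_entropy(ed, sampen_params(config$m, config$eps)))
  imp <- stage("behavior", impute_behavior(behavior, covariates))
  Y <- stage("behavior", quantile_normalize(imp$scores))
  X <- if (is.null(imp$covariates)) NULL else as.matrix(imp$covariates)
  mean_ese <- stage("templates", group_mean_entropy(es, "control"))
  sweep <- stage("templates", sweep_templates(mean_ese, es, Y, X,
                                              densities = config$densities,
                                              n_perm = config$n_perm,
                                              seed = config$seed))
  hen <- sweep$selected$HEN; len <- sweep$selected$LEN
  contrast <- stage("contrast",
                    bootstrap_contrast(Y, X, es, hen$mask, len$mask,
                                       n_boot = config$n_boot,
                                       alpha = config$alpha,
                                       seed = derive_seed(config$seed, 11)))
  out <- list(edge_dynamics_geometry = list(windows = nrow(ed$subjects[[1]]),
                                            edges = nrow(ed$edge_index),
                                            window_frames = ed$window_frames),
              entropy = es, mean_ese = mean_ese, sweep = sweep,
              hen = hen, len = len, behavior = Y, covariates = X,
              contrast = contrast)
  if (!is.null(labels)) {
    net <- list()
    for (tail in c("hen", "len")) {
      mk <- out[[tail]]$mask
      ew <- stage("edgewise", edgewise_variance(Y, X, es, mk))
      net[[tail]] <- list(
        edgewise = ew,
        shuffle = stage("network",
                        null_edge_shuffle(ew$value, mk, labels,
                                          n_perm = config$n_perm_network,
                                          seed = derive_seed(config$seed, 21))),
        rewire = stage("network",
                       null_rewire(ew$value, mk, labels,
                                   n_perm = config$n_perm_network,
                                   seed = derive_seed(config$seed, 22))),
        centrality = stage("topology",
                           degree_centrality(mk, n_perm = config$n_perm_network,
                                             seed = derive_seed(config$seed, 23))))
      net[[tail]]$shuffle_fdr <- fdr_bh(net[[tail]]$shuffle$p, config$q_fdr)
      net[[tail]]$rewire_fdr <- fdr_bh(net[[tail]]$rewire$p, config$q_fdr)
    }
    out$network <- net
    cortical <- which(labels != "SC")
    out$node_entropy <- stage("topology",
                              node_entropy(net$hen$centrality, net$len$centrality,
                                           cortical))
    if (!is.null(maps) && !is.null(coords)) {
      out$map_tests <- stage("maps",
                             map_correlation_test(out$node_entropy, maps,
                                                  coords[cortical, , drop = FALSE],
                                                  n_surr = config$n_surr,
                                                  seed = derive_seed(config$seed, 31),
                                                  q = config$q_fdr))
    }
  }
  out$pca <- stage("pca", first_pc(Y))
  out$manifest <- list(config = unclass(config),
                       n_subjects = length(ts$subjects),
                       n_parcels = length(ts$parcel_ids),
                       seed = config$seed)
  out
}

#' Control experiments: shuffled and random edges
#'
#' Refits the selected HEN/LEN models after destroying the template
#' structure: "shuffled-edges" permutes each patient's masked entropy
#' values independently before building the similarity matrix;
#' "random-edges" replaces the template with a random edge set of the
#' same size, common to all patients.
#'
#' @param bundle result of [run_full]
#' @param es the `entropy_set` (bundle$entropy)
#' @param mode "shuffled-edges" or "random-edges"
#' @param seed RNG seed
#' @param n_perm permutations for the control p-Perm
#' @return list per tail: `fit` (a `varcomp_fit` with `p_perm`)
#' @export
run_controls <- function(bundle, es = bundle$entropy,
                         mode = c("shuffled-edges", "random-edges"),
                         seed = 1L, n_perm = 1000L) {
  mode <- match.arg(mode)
  Y <- bundle$behavior; X <- bundle$covariates
  m <- entropy_matrix(es, "patient")
  out <- list()
  for (tail in c("hen", "len")) {
    mask <- bundle[[tail]]$mask
    set.seed(derive_seed(seed, if (tail == "hen") 1 else 2))
    if (mode == "shuffled-edges") {
      z <- m[, mask$edges, drop = FALSE]
      z <- t(apply(z, 1, sample))
      R <- cor(t(z)); diag(R) <- 1
    } else {
      edges <- sort(sample.int(mask$n_total, length(mask$edges)))
      rmask <- structure(list(tail = mask$tail, density = mask$density,
                              edges = edges, n_total = mask$n_total),
                         class = "template_mask")
      R <- build_similarity(m, rmask, group = "all")$R
    }
    out[[tail]] <- list(fit = ese_variance_model(Y, X, R, n_perm = n_perm,
                                                 seed = derive_seed(seed, 5)),
                        mode = mode)
  }
  out
}
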