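# Independent oracles and small fixture builders used across the suite.

# Brute-force sample entropy: literal double loop over template pairs,
# kept independent of the compiled implementation.
sampen_oracle <- function(x, m = 2L, eps = 0.2) {
  n <- length(x)
  stopifnot(n > m + 1)
  r <- eps * sqrt(mean((x - mean(x))^2))
  nt <- n - m
  bm <- 0L; bm1 <- 0L
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (j == i) next
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        bm <- bm + 1L
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) bm1 <- bm1 + 1L
      }
    }
  }
  if (bm == 0L || bm1 == 0L) return(NA_real_)
  -log(bm1 / bm)
}

# brute-force windowed Pearson correlation for one subject
sliding_cor_oracle <- function(m, w, step = 1L) {
  p <- ncol(m)
  starts <- seq(1, nrow(m) - w + 1, by = step)
  pairs <- t(combn(p, 2))
  out <- matrix(NA_real_, length(starts), nrow(pairs))
  for (k in seq_along(starts)) {
    win <- m[starts[k]:(starts[k] + w - 1), , drop = FALSE]
    for (e in seq_len(nrow(pairs)))
      out[k, e] <- cor(win[, pairs[e, 1]], win[, pairs[e, 2]])
  }
  out
}

# structured unit-diagonal similarity kernel from latent features
make_kernel <- function(n, seed, k = 20) {
  set.seed(seed)
  R <- cor(t(matrix(rnorm(n * k), n, k)))
  diag(R) <- 1
  R
}

# draw Y from the single-kernel generative model at a planted fraction
draw_behavior <- function(fraction, R, P = 7, X = NULL, B = NULL, seed = 1) {
  spec <- planted_behavior_spec(fraction, list(R), P)
  simulate_behavior(X, B, spec$components, spec$Sigma_e, seed = seed)
}

# small planted study shared by the slower pipeline tests (cached per session)
planted_study_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_controls = 10, n_patients = 12, n_parcels = 24,
                        n_frames = 220, tr = 0.8, seed = 101)
      plan <- default_edge_plan(24, n_regular = 4, n_fast_hubs = 2,
                                regular_timescale = 330)
      ts <- simulate_timeseries(cfg, plan)
      ed <- sliding_window_correlation(preprocess_timeseries(ts),
                                       window_seconds = 32, step_frames = 1)
      cache <<- list(cfg = cfg, plan = plan, ts = ts, ed = ed,
                     es = edge_entropy(ed))
    }
    cache
  }
})
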