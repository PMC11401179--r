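test_that("configuration and plan invariants are enforced", {
  expect_error(sim_config(n_controls = 1), "counts")
  expect_error(sim_config(tr = 0), "tr")
  expect_error(edge_plan(1, fast_hubs = 10, n_parcels = 10,
                         regular_timescale = 1.5), "timescale")
  expect_error(edge_plan(1, fast_hubs = 10, n_parcels = 10,
                         regular_timescale = 5, irregular_timescale = 8),
               "exceed")
  # regular edges must be vertex-disjoint and avoid the hubs
  expect_error(edge_plan(c(1, 2), fast_hubs = 10, n_parcels = 10), "disjoint")
  plan <- default_edge_plan(20, n_regular = 3, n_fast_hubs = 2)
  expect_length(plan$regular_edges, 3)
  expect_length(plan$irregular_edges, 2 * 18)
  expect_length(intersect(plan$regular_edges, plan$irregular_edges), 0)
})

test_that("timeseries generation is deterministic and standardized", {
  cfg <- sim_config(n_controls = 2, n_patients = 2, n_parcels = 10,
                    n_frames = 120, seed = 7)
  plan <- default_edge_plan(10, n_regular = 2, n_fast_hubs = 1)
  ts1 <- simulate_timeseries(cfg, plan)
  ts2 <- simulate_timeseries(cfg, plan)
  expect_identical(ts1$subjects, ts2$subjects)
  expect_equal(ncol(ts1$subjects[[1]]), 10)
  expect_equal(nrow(ts1$subjects[[1]]), 120)
  m <- ts1$subjects[[1]]
  expect_lt(max(abs(colMeans(m))), 1e-12)
  expect_equal(apply(m, 2, sd), rep(1, 10), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("planted ESE ordering holds across seeds", {
  hits <- 0L
  n_seeds <- 8
  for (seed in seq_len(n_seeds)) {
    cfg <- sim_config(n_controls = 4, n_patients = 2, n_parcels = 14,
                      n_frames = 160, seed = 200 + seed)
    # modulation period scaled to the short test run so the regular
    # coupling completes most of a cycle
    plan <- default_edge_plan(14, n_regular = 3, n_fast_hubs = 2,
                              regular_timescale = 240)
    ts <- simulate_timeseries(cfg, plan)
    es <- edge_entropy(sliding_window_correlation(preprocess_timeseries(ts),
                                                  window_seconds = 24))
    mu <- colMeans(es$values[es$group == "control", ])
    ok <- mean(mu[plan$regular_edges]) < mean(mu[-c(plan$regular_edges,
                                                    plan$irregular_edges)]) &&
      mean(mu[plan$irregular_edges]) > mean(mu[-c(plan$regular_edges,
                                                  plan$irregular_edges)])
    hits <- hits + ok
  }
  expect_gte(hits, n_seeds - 1)
})

test_that("behavior generator reproduces the Kronecker covariance", {
  # Sigma_e -> 0 with a structured kernel: Cov(Vec(Y - XB)) ~ Sigma_c x R
  n <- 6; P <- 2
  R <- make_kernel(n, 111, k = 3)
  Sc <- matrix(c(1, 0.6, 0.6, 2), 2, 2)
  draws <- vapply(seq_len(5000), function(k)
    as.numeric(simulate_behavior(NULL, NULL, list(list(Sigma = Sc, R = R)),
                                 diag(1e-12, P), seed = 3000 + k)),
    numeric(n * P))
  emp <- cov(t(draws))
  theo <- kronecker(Sc, R)  # Vec stacks columns: measure-major blocks
  expect_lt(max(abs(emp - theo)), 0.1 * max(abs(theo)))
})

test_that("zero structured component leaves only residual covariance", {
  n <- 5; P <- 2
  Se <- matrix(c(1, 0.3, 0.3, 0.5), 2, 2)
  draws <- vapply(seq_len(4000), function(k)
    as.numeric(simulate_behavior(NULL, NULL,
                                 list(list(Sigma = diag(0, P), R = diag(n))),
                                 Se, seed = 5000 + k)),
    numeric(n * P))
  emp <- cov(t(draws))
  theo <- kronecker(Se, diag(n))
  expect_lt(max(abs(emp - theo)), 0.12 * max(abs(theo)))
})

test_that("non-PSD kernels are rejected with the offending eigenvalue", {
  R_bad <- matrix(c(1, 2, 2, 1), 2, 2)  # eigenvalue -1
  expect_error(simulate_behavior(NULL, NULL,
                                 list(list(Sigma = diag(2), R = R_bad)),
                                 diag(2), seed = 1),
               "positive semi-definite \\(eigenvalue")
})

test_that("annotation maps are standardized, autocorrelated and deterministic", {
  coords <- simulate_parcel_coords(simulate_network_labels(50), seed = 9)
  m1 <- simulate_annotation_map(coords, range_param = 20, seed = 10)
  m2 <- simulate_annotation_map(coords, range_param = 20, seed = 10)
  expect_identical(m1, m2)
  expect_equal(mean(m1), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((m1 - mean(m1))^2)), 1, tolerance = 1e-12)
  expect_error(simulate_annotation_map(coords, 0), "positive")
  # white limit: successive maps uncorrelated
  r <- vapply(1:50, function(k) {
    a <- simulate_annotation_map(coords, 1e-6, seed = 2 * k)
    b <- simulate_annotation_map(coords, 1e-6, seed = 2 * k + 1)
    cor(a, b)
  }, numeric(1))
  expect_lt(median(abs(r)), 0.15)
  # long range: smoother than white between nearest neighbors
  D <- as.matrix(dist(coords))
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  smooth <- simulate_annotation_map(coords, 200, seed = 11)
  white <- simulate_annotation_map(coords, 1e-6, seed = 11)
  expect_lt(var(smooth - smooth[nn]), var(white - white[nn]))
})

test_that("network labels cover the 8 systems and round-trip through files", {
  lab <- simulate_network_labels(116)
  expect_equal(length(lab), 116)
  expect_setequal(unique(lab), SYSTEM_LABELS)
  expect_true(all(table(lab) >= 1))
  expect_equal(sort(as.vector(table(simulate_network_labels(8)))), rep(1L, 8))
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(parcel = seq_along(lab), label = lab), f, row.names = FALSE)
  expect_identical(read.csv(f, stringsAsFactors = FALSE)$label, lab)
  unlink(f)
})

test_that("covariates mirror the study's distributional shapes", {
  cv <- simulate_covariates(5000, seed = 12)
  expect_equal(mean(cv$age), 22.65, tolerance = 0.3)
  expect_equal(mean(cv$sex), 0.37, tolerance = 0.05)
  expect_true(all(cv$medication >= 0))
  expect_true(all(cv$fd > 0))
  expect_equal(mean(cv$fd), 0.12, tolerance = 0.02)
  expect_setequal(unique(cv$phenotype), c(0, 1))
})
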