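# toy geometry: 4 parcels in 2 systems, mask by hand
toy_mask <- function(edges, n_parcels = 4) {
  structure(list(tail = "HEN", density = length(edges) / n_edges_of(n_parcels),
                 edges = as.integer(edges), n_total = n_edges_of(n_parcels)),
            class = "template_mask")
}
n_edges_of <- function(p) p * (p - 1) / 2

test_that("block averages match a hand calculation on a toy graph", {
  labels <- c("VIS", "VIS", "SC", "SC")
  # canonical edges for P=4: (1,2) (1,3) (1,4) (2,3) (2,4) (3,4)
  mask <- toy_mask(c(1, 3, 4))
  ba <- block_average(c(1, 2, 3), mask, labels)
  expect_equal(ba$mean["VIS", "VIS"], 1)
  expect_equal(ba$mean["VIS", "SC"], 2.5)
  expect_equal(ba$mean["SC", "VIS"], 2.5)
  expect_true(is.na(ba$mean["SC", "SC"]))
  expect_equal(ba$count["VIS", "SC"], 2)
})

test_that("constant edge values give constant block means and calibrated nulls", {
  labels <- simulate_network_labels(12)
  mask <- proportional_threshold(seq_len(n_edges_of(12)), 0.5, "HEN")
  ba <- block_average(rep(3, length(mask$edges)), mask, labels)
  expect_true(all(ba$mean[!is.na(ba$mean)] == 3))
  ns <- null_edge_shuffle(rep(3, length(mask$edges)), mask, labels,
                          n_perm = 200, seed = 1)
  expect_true(all(ns$p[!is.na(ns$p)] > 0.05))  # nothing can exceed a constant
})

test_that("edge shuffle preserves edge count and add-one keeps p positive", {
  set.seed(71)
  labels <- simulate_network_labels(15)
  E <- n_edges_of(15)
  mask <- proportional_threshold(rnorm(E), 0.3, "HEN")
  vals <- rnorm(length(mask$edges))
  ns <- null_edge_shuffle(vals, mask, labels, n_perm = 150, seed = 2)
  expect_true(all(ns$p[!is.na(ns$p)] > 0))
  expect_true(all(ns$p[!is.na(ns$p)] >= 1 / 151))
})

test_that("value permutation and relocation nulls agree on a planted block", {
  set.seed(72)
  labels <- simulate_network_labels(16)
  E <- n_edges_of(16)
  ei <- edge_index(16)
  mask <- proportional_threshold(seq_len(E), 1, "HEN")  # all edges
  li <- match(labels, SYSTEM_LABELS)
  vals <- rnorm(E)
  planted <- li[ei$i] == 1 & li[ei$j] == 1  # VIS-VIS block
  vals[planted] <- vals[planted] + 3
  for (relocate in c(TRUE, FALSE)) {
    ns <- null_edge_shuffle(vals, mask, labels, n_perm = 500, seed = 3,
                            relocate = relocate)
    expect_lt(ns$p["VIS-VIS"], 0.01)
  }
})

test_that("rewiring preserves degrees exactly and keeps strength ranking", {
  set.seed(73)
  P <- 20
  E <- n_edges_of(P)
  mask <- proportional_threshold(rnorm(E), 0.25, "HEN")
  vals <- abs(rnorm(length(mask$edges)))
  labels <- simulate_network_labels(P)
  ei <- edge_index(P)
  deg0 <- tabulate(c(ei$i[mask$edges], ei$j[mask$edges]), P)
  nr <- null_rewire(vals, mask, labels, n_perm = 100, seed = 4)
  expect_true(all(nr$strength_spearman > 0.5))
  expect_gt(median(nr$strength_spearman), 0.8)
  # degree preservation is a hard igraph constraint; verify on one rewire
  g0 <- igraph::graph_from_edgelist(cbind(ei$i[mask$edges], ei$j[mask$edges]),
                                    directed = FALSE)
  g1 <- igraph::rewire(g0, igraph::keeping_degseq(niter = 200))
  expect_equal(igraph::degree(g1), igraph::degree(g0))
})

test_that("star graphs cannot be rewired", {
  P <- 8
  star <- edge_position_star <- which(edge_index(P)$i == 1)
  mask <- toy_mask(star, P)
  expect_error(null_rewire(rnorm(length(star)), mask,
                           simulate_network_labels(P), n_perm = 100),
               "constrained")
})

test_that("BH step-up matches the hand calculation and dominates Bonferroni", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.5), 0.05), c(TRUE, TRUE, FALSE))
  expect_equal(fdr_bh(rep(1, 5)), rep(FALSE, 5))
  set.seed(74)
  p <- runif(50)^2
  bh <- fdr_bh(p, 0.05)
  bonf <- p <= 0.05 / length(p)
  expect_true(all(bh[bonf]))
  expect_true(is.na(fdr_bh(c(0.1, NA))[2]))
})

test_that("degree centrality normalizes against the density-matched null", {
  P <- 10
  full <- toy_mask(seq_len(n_edges_of(P)), P)
  dc <- degree_centrality(full, n_perm = 50, seed = 5)
  expect_equal(dc$normalized, rep(1, P))  # complete graph equals its null
  expect_equal(sum(dc$degree), 2 * length(full$edges))
  # planted hub
  ei <- edge_index(12)
  hub_edges <- which(ei$i == 1 | ei$j == 1)
  spoke <- toy_mask(c(hub_edges, 40), 12)
  dc2 <- degree_centrality(spoke, n_perm = 2000, seed = 6)
  expect_gt(dc2$normalized[1], 2)
  expect_lt(dc2$p[1], 0.01)
  # null mean approximates 2|mask|/P
  expect_equal(mean(dc2$null_mean), 2 * length(spoke$edges) / 12, tolerance = 0.02)
})

test_that("node entropy rescales the centrality difference to [0, 1]", {
  ch <- data.frame(parcel = 1:6, normalized = c(2, 1, 1, 1, 1, 0.5))
  cl <- data.frame(parcel = 1:6, normalized = c(0.5, 1, 1, 1, 1, 2))
  ne <- node_entropy(ch, cl, 1:6)
  expect_equal(unname(ne[1]), 1)
  expect_equal(unname(ne[6]), 0)
  ne_swap <- node_entropy(cl, ch, 1:6)
  expect_equal(unname(ne_swap), unname(1 - ne))
  expect_error(node_entropy(ch, ch, 1:6), "degenerate")
})
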