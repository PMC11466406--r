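test_that("Poisson tail p-values are exact", {
  expect_equal(poisson_tail_p(0, 0.5, 10), 1)
  expect_equal(poisson_tail_p(2, 0.1, 1), 1 - exp(-0.1) * 1.1,
               tolerance = 1e-12)
  expect_error(poisson_tail_p(-1, 0.1, 1), "nonnegative")
  expect_error(poisson_tail_p(1, -0.1, 1), "nonnegative")
})

test_that("BY adjustment reproduces the hand-computed step-up", {
  expect_equal(adjust_by(0.2), 0.2)  # c(1) = 1
  q <- adjust_by(c(0.01, 0.02, 0.03))
  expect_equal(q, rep(0.01 * 3 * (11 / 6), 3), tolerance = 1e-12)
  p <- c(0.04, 0.001, 0.2, 0.01)
  expect_equal(adjust_by(p), adjust_by(rev(p))[4:1])
  expect_true(all(adjust_by(p) >= p))
})

test_that("ensemble counts are bounded and recountable from the specimens", {
  sim <- planted_sim()
  sm <- planted_smoothed()
  cfg <- resampling_config(k = 10, N = 300, M = 5, M_hat = 10, K = 2,
                           n_hvg = 150, seed = 21)
  ens <- run_grn_ensemble(sm, sim$tfs, cfg)
  expect_lte(max(ens$node_count), ens$M_effective)
  expect_lte(max(ens$edge_count), ens$M_effective)
  # recount nodes and edges directly from the specimen graphs
  graphs <- Filter(Negate(is.null), ens$graphs)
  node_re <- table(unlist(lapply(graphs, function(g) igraph::V(g)$name)))
  expect_equal(ens$node_count[sort(names(ens$node_count))],
               stats::setNames(as.integer(node_re), names(node_re))[
                 sort(names(node_re))])
  edge_re <- table(unlist(lapply(graphs, edge_keys_of)))
  expect_equal(ens$edge_count[sort(names(ens$edge_count))],
               stats::setNames(as.integer(edge_re), names(edge_re))[
                 sort(names(edge_re))])
})

test_that("M = 1 gives 0/1 support counts", {
  sim <- planted_sim()
  sm <- planted_smoothed()
  cfg <- resampling_config(k = 10, N = 300, M = 1, M_hat = 10, K = 2,
                           n_hvg = 150, seed = 22)
  ens <- run_grn_ensemble(sm, sim$tfs, cfg)
  expect_true(all(ens$node_count %in% 0:1))
  expect_true(all(ens$edge_count %in% 0:1))
})

test_that("the analytic node null rate is n_hvg / n_genes", {
  sim <- planted_sim()
  sm <- planted_smoothed()
  cfg <- resampling_config(k = 10, N = 300, M = 2, M_hat = 2, K = 2,
                           n_hvg = 200, seed = 23)
  nul <- run_null_ensemble(sm, sim$tfs, cfg)
  expect_equal(nul$lambda_node, 200 / 1000)
  expect_gte(nul$lambda_edge, 0)
  expect_equal(nul$n_candidate_pairs, choose(length(sim$tfs), 2))
})

test_that("the consensus applies the q filter and endpoint closure", {
  # hand-built ensemble: edge a|b has massive support, node b does not
  fake <- list(
    node_count = c(a = 20L, b = 1L, c = 20L),
    edge_count = c("a|b" = 20L, "a|c" = 20L),
    edge_mi_sum = c("a|b" = 10, "a|c" = 14),
    M_effective = 20L,
    cfg = resampling_config(seed = 1)
  )
  rates <- list(lambda_node = 0.05, lambda_edge = 1e-4)
  cons <- consensus_grn(fake, rates, q_threshold = 1e-5)
  expect_setequal(igraph::V(cons$graph)$name, c("a", "c"))
  expect_equal(edge_keys_of(cons$graph), "a|c")          # a|b lost endpoint b
  expect_equal(igraph::E(cons$graph)$weight, 14 / 20)    # mean MI
  sup <- cons$support
  expect_true(all(sup$q >= sup$p))
  expect_equal(sup$count[sup$id == "a|c"], 20L)
  # with everything insignificant the graph is empty (and warns)
  rates_high <- list(lambda_node = 0.9, lambda_edge = 0.9)
  expect_warning(cons2 <- consensus_grn(fake, rates_high, q_threshold = 1e-5),
                 "empty")
  expect_equal(igraph::vcount(cons2$graph), 0L)
})

test_that("null calibration: independent genes yield few small edge p-values", {
  # On shuffled-name nulls the Poisson model must not be anti-conservative:
  # the per-pair appearance probability implied by lambda_edge must bound
  # the observed per-pair rates (pooled estimate vs empirical recounts).
  nd <- simulate_null_dataset(n_cells = 300, n_genes = 150, seed = 31)
  cfg <- resampling_config(k = 5, N = 100, M = 5, M_hat = 30, K = 5,
                           n_hvg = 50, seed = 31)
  sm <- knn_smooth(nd$counts, nd$embedding, 5)
  nul <- run_null_ensemble(sm, nd$tfs, cfg, per_pair = TRUE)
  # pooled rate equals total edges / (specimens x candidate pairs)
  expect_equal(nul$lambda_edge,
               nul$total_null_edges / (nul$n_specimens * nul$n_candidate_pairs))
  if (length(nul$pair_count)) {
    # no single named pair recurs in any sizeable fraction of the shuffled
    # specimens (name shuffling destroys pair identity)
    expect_lte(max(nul$pair_count), 0.1 * nul$n_specimens)
  }
})

test_that("specimen seeds derive independently of loop order", {
  s1 <- grnboot:::derive_seeds(99, 10, stream = 1L)
  s2 <- grnboot:::derive_seeds(99, 4, stream = 1L)
  expect_equal(s1[1:4], s2)
  expect_false(any(grnboot:::derive_seeds(99, 10, stream = 2L) == s1))
})
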