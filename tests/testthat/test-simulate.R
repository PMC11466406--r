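test_that("generators are bitwise-deterministic given the seed", {
  a <- simulate_dataset(n_cells = 100, n_genes = 300, seed = 5)
  b <- simulate_dataset(n_cells = 100, n_genes = 300, seed = 5)
  expect_identical(unclass(a$counts), unclass(b$counts))
  expect_identical(unclass(a$embedding), unclass(b$embedding))
  expect_identical(a$truth$edges, b$truth$edges)
  c <- simulate_dataset(n_cells = 100, n_genes = 300, seed = 6)
  expect_false(identical(unclass(a$counts), unclass(c$counts)))
  g1 <- simulate_random_graph(15, 0.3, seed = 2)
  g2 <- simulate_random_graph(15, 0.3, seed = 2)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  p1 <- simulate_profile_blocks(10, 20, 3, 5, seed = 3)
  p2 <- simulate_profile_blocks(10, 20, 3, 5, seed = 3)
  expect_identical(p1$profiles, p2$profiles)
  expect_identical(p1$labels, p2$labels)
})

test_that("planted structure is well-formed", {
  sim <- simulate_dataset(n_cells = 200, n_genes = 300, seed = 9)
  ed <- sim$truth$edges
  expect_true(all(ed$regulator %in% sim$tfs))
  expect_true(all(ed$target %in% sim$tfs))
  expect_equal(nrow(ed), 3 * 5 * 10)
  expect_length(unlist(sim$truth$regulators), 15)
  expect_true(all(lengths(sim$truth$regulators) >= 1))
  expect_setequal(names(sim$truth$cell_type), rownames(sim$counts))
  expect_error(simulate_dataset(n_genes = 100, seed = 1), "gene budget")
})

test_that("negative-binomial marginals match the requested moments", {
  nd <- simulate_null_dataset(n_cells = 10000, n_genes = 40,
                              nb_dispersion = 0.5, seed = 10)
  x <- unclass(nd$counts)
  mu_hat <- colMeans(x)
  v_hat <- apply(x, 2, var)
  disp_hat <- (v_hat - mu_hat) / mu_hat^2
  # recover dispersion within 5% on average over well-expressed genes
  hi <- mu_hat > 1
  expect_lt(abs(mean(disp_hat[hi]) - 0.5) / 0.5, 0.05)
  expect_true(all(v_hat[hi] > mu_hat[hi]))  # overdispersed throughout
})

test_that("random graphs hit their edge-probability extremes and mean", {
  expect_equal(igraph::ecount(simulate_random_graph(10, 0, seed = 1)), 0L)
  full <- simulate_random_graph(10, 1, seed = 1)
  expect_equal(igraph::ecount(full), choose(10, 2))
  expect_equal(enumerate_optimal_mds(full)$mds_size, 1L)
  ecounts <- vapply(1:50, function(s)
    igraph::ecount(simulate_random_graph(12, 0.3, seed = s)), numeric(1))
  expect_lt(abs(mean(ecounts) - 0.3 * choose(12, 2)), 2)
})

test_that("removing the signal removes the planted co-expression", {
  # effect off and transmission noise large: regulator-target correlation on
  # smoothed data collapses toward the background level
  sim0 <- simulate_dataset(n_cells = 400, n_genes = 200, n_types = 2,
                           n_regulators = 2, targets_per_regulator = 5,
                           effect_size = 0, noise_sd = 50, seed = 12)
  sm0 <- knn_smooth(sim0$counts, sim0$embedding, 10)
  ed <- sim0$truth$edges
  cors <- mapply(function(r, t) abs(cor(unclass(sm0)[, r], unclass(sm0)[, t])),
                 ed$regulator, ed$target)
  expect_lt(median(cors), 0.2)
})

test_that("block profiles carry their labels and separation", {
  pb <- simulate_profile_blocks(20, 100, 4, sep = 10, seed = 13)
  expect_equal(dim(pb$profiles), c(20L, 100L))
  expect_equal(length(unique(pb$labels)), 4L)
  # within-block correlation far above between-block correlation
  cc <- cor(t(pb$profiles))
  same <- outer(pb$labels, pb$labels, "==")
  diag(same) <- NA
  expect_gt(mean(cc[same & !is.na(same)]), 0.9)
  expect_lt(abs(mean(cc[!same & !is.na(same)])), 0.2)
})
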