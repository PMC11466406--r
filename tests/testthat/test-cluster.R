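fake_clumps <- function(labels) {
  structure(list(labels = labels, resolution = 1,
                 min_size = min(table(labels)),
                 n_clumps = length(unique(labels)), size_floor = 1),
            class = "clump_partition")
}

test_that("clump profiles average cells per clump", {
  expr <- matrix(c(1, 3, 5, 3, 5, 7), 3, 2,
                 dimnames = list(c("c1", "c2", "c3"), c("gA", "gB")))
  cl <- fake_clumps(c(c1 = 1L, c2 = 1L, c3 = 2L))
  prof <- clump_profiles(expr, cl, c("gA", "gB"))
  expect_equal(unname(prof["clump1", ]), c(2, 4))  # means of (1,3) and (3,5)
  expect_equal(unname(prof["clump2", ]), c(5, 7))  # single-cell clump
  expect_error(clump_profiles(expr, cl, c("gA", "nope")), "nope")
})

test_that("identical cells give identical profile rows", {
  expr <- matrix(2, 6, 3, dimnames = list(paste0("c", 1:6), paste0("g", 1:3)))
  cl <- fake_clumps(stats::setNames(rep(1:3, each = 2), paste0("c", 1:6)))
  prof <- clump_profiles(expr, cl, paste0("g", 1:3))
  expect_true(all(prof == 2))
})

test_that("Ward tree orders forced configurations correctly", {
  # rows 1,2 perfectly correlated, row 3 anti-correlated with both
  prof <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1))
  rownames(prof) <- paste0("clump", 1:3)
  hc <- ward_tree(prof)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))  # identical pair merges first
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_equal(cut_clusters(hc, 2)[["clump3"]],
               3 - cut_clusters(hc, 2)[["clump1"]])  # 3 is apart
  expect_error(ward_tree(rbind(c(1, 1, 1), c(1, 2, 3))), "zero-variance")
})

test_that("Ward heights match an independent Lance-Williams implementation", {
  set.seed(11)
  prof <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("clump", 1:6), NULL))
  d <- stats::as.dist(1 - stats::cor(t(prof)))
  hc <- ward_tree(prof)
  expect_equal(sort(hc$height), lw_ward_heights(d), tolerance = 1e-10)
})

test_that("tree cuts behave at the extremes", {
  set.seed(12)
  prof <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("clump", 1:8), NULL))
  hc <- ward_tree(prof)
  expect_equal(unname(cut_clusters(hc, 1)), rep(1L, 8))
  expect_equal(sort(unname(cut_clusters(hc, 8))), 1:8)
  expect_error(cut_clusters(hc, 9), "out of range")
})

test_that("ARI closed forms and symmetry hold", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(rep(1, 6), 1:6), 0)  # degenerate -> 0
  # contingency [[2,0],[1,1]]: direct Hubert-Arabie evaluation
  a <- c(1, 1, 1, 2)
  b <- c(1, 1, 2, 2)
  sum_ij <- choose(2, 2) + choose(1, 2) + choose(1, 2)
  ea <- choose(3, 2) + choose(1, 2)
  eb <- choose(2, 2) + choose(2, 2)
  expected <- ea * eb / choose(4, 2)
  manual <- (sum_ij - expected) / ((ea + eb) / 2 - expected)
  expect_equal(adjusted_rand_index(a, b), manual, tolerance = 1e-12)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
})

test_that("ARI agrees with the mclust reference on random partitions", {
  set.seed(13)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("named partitions are matched by member, not position", {
  a <- stats::setNames(c(1, 1, 2), c("x", "y", "z"))
  b <- stats::setNames(c(2, 1, 1), c("z", "x", "y"))  # same partition
  expect_equal(adjusted_rand_index(a, b), 1)
  expect_error(adjusted_rand_index(a, stats::setNames(1:3, c("x", "y", "w"))),
               "different member")
})

test_that("cell expansion inherits and merges clump labels", {
  cl <- fake_clumps(stats::setNames(c(1L, 1L, 2L, 3L), paste0("c", 1:4)))
  clust <- stats::setNames(c(1L, 1L, 2L), paste0("clump", 1:3))  # merge 1+2
  cells <- expand_to_cells(cl, clust)
  expect_equal(unname(cells), c(1L, 1L, 1L, 2L))
  expect_error(expand_to_cells(cl, clust[1:2]), "every clump")
})

test_that("confident-cluster extraction reports outermost nodes below the root", {
  prof <- simulate_profile_blocks(12, 40, 3, sep = 10, seed = 44)$profiles
  ms <- multiscale_bootstrap(prof, B = 200, seed = 44)
  # forge AU values to exercise the walk independently of the bootstrap:
  # root stays unreported even with AU 1; nested significant nodes collapse
  # to the outermost one
  n <- length(ms$hclust$order)
  ms2 <- ms
  ms2$au <- rep(0, n - 1)
  expect_true(all(is.na(pick_confident(ms2))))
  # make one root child's whole subtree significant: only the child reported
  root_kids <- ms$hclust$merge[n - 1, ]
  kid <- max(root_kids)  # an internal child
  ms3 <- ms
  ms3$au <- rep(0.99, n - 1)
  conf <- pick_confident(ms3, alpha = 0.05)
  cl <- attr(conf, "clusters")
  expect_equal(length(cl), 2)  # the two root children, nothing nested
  expect_setequal(unlist(cl), seq_len(n))
})

test_that("choose_k picks the smallest k at maximal agreement", {
  prof <- simulate_profile_blocks(15, 50, 3, sep = 10, seed = 45)$profiles
  ms <- multiscale_bootstrap(prof, B = 300, seed = 45)
  conf <- pick_confident(ms)
  k <- choose_k(ms, conf)
  expect_equal(as.integer(k), 3L)
  expect_equal(max(attr(k, "ari")), attr(k, "ari")[["3"]])
  # explicit tie: confident partition equal to the k = 2 cut means every
  # k >= 2 that reproduces it ties; the smallest wins
  ms_tie <- ms
  ms_tie$au <- rep(0, length(ms$au))
  expect_error(choose_k(ms_tie, pick_confident(ms_tie)), "manually")
})
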