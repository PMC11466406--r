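test_that("sample_cells draws without replacement and is seed-deterministic", {
  set.seed(1)
  cm <- count_matrix(matrix(rpois(40, 3), 10, 4))
  s1 <- with_seed_local(9, sample_cells(cm, 10))
  expect_setequal(rownames(s1), rownames(cm))   # N = n is a permutation
  s2 <- with_seed_local(5, sample_cells(cm, 4))
  s3 <- with_seed_local(5, sample_cells(cm, 4))
  expect_identical(unclass(s2), unclass(s3))
  expect_error(sample_cells(cm, 11), "exceeds")
})

test_that("single-draw frequencies are uniform over cells", {
  cm <- count_matrix(matrix(0:7, 4, 2))
  hits <- with_seed_local(2, {
    draws <- replicate(10000, rownames(sample_cells(cm, 1)))
    table(draws) / 10000
  })
  expect_true(all(abs(hits - 0.25) < 0.02))
})

test_that("shuffling permutes names only and conserves values", {
  set.seed(3)
  cm <- count_matrix(matrix(rpois(50, 4), 5, 10))
  sh <- with_seed_local(7, shuffle_gene_names(cm))
  expect_setequal(colnames(sh), colnames(cm))
  expect_identical(unname(unclass(sh)), unname(unclass(cm)))
  one <- count_matrix(matrix(1:3, 3, 1), gene_ids = "only")
  expect_identical(shuffle_gene_names(one), one)
  sh2 <- with_seed_local(7, shuffle_gene_names(cm))
  expect_identical(colnames(sh2), colnames(sh))
})

test_that("equal-width binning maps ranges as specified", {
  b <- discretize_equal_width(matrix(0:9, 10, 1), 2)
  expect_equal(as.vector(b), rep(0:1, each = 5))
  const <- discretize_equal_width(matrix(5, 8, 1), 4)
  expect_true(all(const == 0))
  set.seed(4)
  x <- matrix(rnorm(300), 100, 3)
  b5 <- discretize_equal_width(x, 5)
  for (j in 1:3) {
    expect_equal(b5[which.min(x[, j]), j], 0L)
    expect_equal(b5[which.max(x[, j]), j], 4L)
  }
  expect_true(all(b5 >= 0 & b5 <= 4))
})

test_that("Miller-Madow MI matches the closed form on the balanced example", {
  x <- rep(c(0, 1), each = 5)
  expect_equal(mi_miller_madow(x, x), log(2) + 0.05, tolerance = 1e-12)
  expect_equal(mi_miller_madow(rep(1, 10), rep(c(0, 1), 5)), 0,
               tolerance = 1e-12)
  expect_error(mi_miller_madow(1:3, 1:4), "equal length")
})

test_that("the C++ MI kernel agrees with the R implementation", {
  set.seed(5)
  bins <- matrix(sample(0:3, 200, replace = TRUE), 50, 4)
  mim <- cpp_mi_matrix_r(bins, 4L)
  for (a in 1:3) {
    for (b in (a + 1):4) {
      expect_equal(mim[a, b], mi_miller_madow(bins[, a], bins[, b]),
                   tolerance = 1e-12)
    }
  }
})

test_that("MI of independent variables is near zero after correction", {
  mis <- with_seed_local(6, replicate(20, {
    x <- sample(0:4, 10000, replace = TRUE)
    y <- sample(0:4, 10000, replace = TRUE)
    mi_miller_madow(x, y)
  }))
  # corrected estimator is centred at 0; 3 SE bound on the mean
  expect_lt(abs(mean(mis)), 3 * sd(mis) / sqrt(length(mis)))
})

test_that("DPI prunes the indirect edge of a noisy chain", {
  pruned <- with_seed_local(7, replicate(10, {
    n <- 2000
    x <- rnorm(n)
    y <- x + rnorm(n, 0, 0.5)
    z <- y + rnorm(n, 0, 0.5)
    expr <- cbind(X = x, Y = y, Z = z)
    g <- aracne_network(expr, B = 10, dpi_eps = 0)
    !igraph::are_adjacent(g, "X", "Z") &&
      igraph::are_adjacent(g, "X", "Y") &&
      igraph::are_adjacent(g, "Y", "Z")
  }))
  expect_gte(mean(pruned), 0.9)
})

test_that("dpi_eps = Inf disables pruning entirely", {
  set.seed(8)
  expr <- matrix(rnorm(400), 100, 4,
                 dimnames = list(NULL, paste0("g", 1:4)))
  g_inf <- aracne_network(expr, B = 6, dpi_eps = Inf)
  bins <- discretize_equal_width(expr, 6)
  mi <- cpp_mi_matrix_r(bins, 6L)
  expect_equal(igraph::ecount(g_inf), sum(mi[upper.tri(mi)] > 0))
})

test_that("only a genuinely coupled pair survives consensus-style repetition", {
  hits <- with_seed_local(9, replicate(20, {
    n <- 2000
    a <- rnorm(n)
    expr <- cbind(A = a, B = a + rnorm(n, 0, 0.4), C = rnorm(n), D = rnorm(n))
    g <- aracne_network(expr, B = 10, dpi_eps = 0)
    w <- igraph::E(g)$weight
    ab <- igraph::are_adjacent(g, "A", "B")
    strongest <- which.max(w)
    ee <- igraph::as_edgelist(g)[strongest, ]
    ab && setequal(ee, c("A", "B"))
  }))
  expect_gte(mean(hits), 0.95)
})
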