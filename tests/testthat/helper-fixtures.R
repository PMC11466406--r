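# Shared fixtures, built lazily and cached for the whole test session.
# All randomness is seeded; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the standard planted fixture (3 types, 5 regulators/type, 10 targets each)
planted_sim <- function() memo("planted_sim", function() {
  simulate_dataset(seed = 7)
})

planted_smoothed <- function() memo("planted_smoothed", function() {
  sim <- planted_sim()
  knn_smooth(sim$counts, sim$embedding, 10)
})

# reduced-scale pipeline configuration used throughout the tests
test_config <- function(seed = 11L) {
  resampling_config(k = 10, N = 500, M = 20, M_hat = 100, K = 10,
                    n_hvg = 200, seed = seed)
}

# unordered edge keys of the planted regulator-target pairs
planted_edge_keys <- function() {
  ed <- planted_sim()$truth$edges
  paste(pmin(ed$regulator, ed$target), pmax(ed$regulator, ed$target),
        sep = "|")
}

edge_keys_of <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  ee <- igraph::as_edgelist(g)
  paste(pmin(ee[, 1], ee[, 2]), pmax(ee[, 1], ee[, 2]), sep = "|")
}

# ten independent GRN-stage replicates on the planted fixture, shared by the
# reproducibility analyses (consensus + the first raw specimen of each)
planted_replicates <- function() memo("planted_replicates", function() {
  sim <- planted_sim()
  sm <- planted_smoothed()
  lapply(1:10, function(i) {
    cfg <- test_config(seed = 300L + i)
    ens <- run_grn_ensemble(sm, sim$tfs, cfg)
    nul <- run_null_ensemble(sm, sim$tfs, cfg)
    cons <- consensus_grn(ens, nul)
    raw <- Filter(Negate(is.null), ens$graphs)[[1]]
    list(consensus = cons, raw_specimen = raw)
  })
})

# run expr under a local seed, restoring the caller's RNG state
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# direct access to the compiled MI kernel for cross-checks
cpp_mi_matrix_r <- function(bins, B) grnboot:::cpp_mi_matrix(bins, B)

# small named igraph from an edge list given as c("a","b", "b","c", ...)
graph_from_pairs <- function(pairs, isolated = character(0)) {
  verts <- unique(c(pairs, isolated))
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = verts)
  if (length(pairs))
    g <- igraph::add_edges(g, match(pairs, verts))
  g
}

mean_pairwise_ari <- function(parts) {
  n <- length(parts)
  v <- c()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      v <- c(v, adjusted_rand_index(parts[[a]], parts[[b]]))
    }
  }
  mean(v)
}

# textbook Lance-Williams Ward implementation (independent oracle for
# ward_tree heights); operates on a squared-dissimilarity update, i.e. the
# ward.D2 convention: heights are sqrt of the accumulated criterion
lw_ward_heights <- function(d) {
  dm <- as.matrix(d)^2
  n <- nrow(dm)
  size <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf
    bi <- bj <- 0
    for (i in which(active)) {
      for (j in which(active)) {
        if (j <= i) next
        if (dm[i, j] < best) {
          best <- dm[i, j]
          bi <- i
          bj <- j
        }
      }
    }
    heights[step] <- sqrt(best)
    # Lance-Williams update for Ward's criterion
    for (k in which(active)) {
      if (k == bi || k == bj) next
      ai <- (size[bi] + size[k]) / (size[bi] + size[bj] + size[k])
      aj <- (size[bj] + size[k]) / (size[bi] + size[bj] + size[k])
      bcoef <- -size[k] / (size[bi] + size[bj] + size[k])
      dm[bi, k] <- dm[k, bi] <- ai * dm[bi, k] + aj * dm[bj, k] +
        bcoef * dm[bi, bj]
    }
    size[bi] <- size[bi] + size[bj]
    active[bj] <- FALSE
  }
  sort(heights)
}
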