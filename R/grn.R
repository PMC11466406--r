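#' Resample cells from a count matrix
#'
#' Draws `N` cells uniformly, by default without replacement (the pipeline
#' subsamples one third to one half of the cells per specimen).
#'
#' @param counts a [count_matrix].
#' @param N number of cells to draw.
#' @param replace draw with replacement (bootstrap) instead.
#' @return A [count_matrix] with `N` rows. With `replace = TRUE` duplicated
#'   cells get suffixed ids to keep row ids unique.
#' @export
sample_cells <- function(counts, N, replace = FALSE) {
  stopifnot(is_count_matrix(counts))
  n <- nrow(counts)
  if (!replace && N > n) stop("N exceeds the number of cells")
  idx <- sample.int(n, N, replace = replace)
  vals <- unclass(counts)[idx, , drop = FALSE]
  ids <- rownames(counts)[idx]
  if (replace) ids <- make.unique(ids)
  count_matrix(vals, cell_ids = ids, gene_ids = colnames(counts))
}

#' Shuffle gene names
#'
#' Permutes the gene identifiers uniformly at random while leaving the values
#' untouched; the null device of the significance layer.
#'
#' @param counts a [count_matrix].
#' @return A [count_matrix] with permuted `gene_ids`.
#' @export
shuffle_gene_names <- function(counts) {
  stopifnot(is_count_matrix(counts))
  g <- ncol(counts)
  count_matrix(unclass(counts), cell_ids = rownames(counts),
               gene_ids = colnames(counts)[sample.int(g, g)])
}

#' Equal-width discretization
#'
#' Splits each gene's observed range `[min, max]` into `B` equal intervals;
#' the maximum maps to bin `B - 1`; a constant gene maps entirely to bin 0.
#'
#' @param m numeric matrix, cells x genes.
#' @param B number of bins, `>= 2`.
#' @return Integer matrix of bin indices in `[0, B)` with attribute
#'   `n_bins = B`.
#' @export
discretize_equal_width <- function(m, B) {
  stopifnot(B >= 2)
  m <- as.matrix(unclass(m))
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1  # constant gene -> all bin 0
  z <- sweep(sweep(m, 2, lo, "-"), 2, rng, "/")
  bins <- pmin(floor(z * B), B - 1)
  storage.mode(bins) <- "integer"
  attr(bins, "n_bins") <- as.integer(B)
  bins
}

#' Miller-Madow mutual information of two discrete vectors
#'
#' `MI = H(x) + H(y) - H(x, y)` with each entropy estimated by the plugin
#' estimator plus the Miller-Madow bias correction `(m - 1) / (2n)`, where
#' `m` is the number of occupied cells. Natural-log units; small negative
#' values are possible and are clipped at zero only when building networks.
#'
#' @param x,y equal-length vectors of discrete values (any type coercible to
#'   factor).
#' @return The Miller-Madow MI estimate (numeric scalar).
#' @export
mi_miller_madow <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  hx <- entropy_mm_r(table(x), n)
  hy <- entropy_mm_r(table(y), n)
  hxy <- entropy_mm_r(table(x, y), n)
  hx + hy - hxy
}

entropy_mm_r <- function(tab, n) {
  cnt <- as.numeric(tab)
  cnt <- cnt[cnt > 0]
  p <- cnt / n
  -sum(p * log(p)) + (length(cnt) - 1) / (2 * n)
}

#' ARACNe mutual-information network
#'
#' Computes the all-pairs Miller-Madow MI matrix on equal-width bins, removes
#' edges with `MI <= 0`, and applies data-processing-inequality pruning: in
#' every triangle the strictly weakest edge (by more than `dpi_eps`) is
#' removed. With fewer than three genes the MI graph is returned without DPI
#' (with a warning).
#'
#' @param expr numeric matrix, cells x genes, with gene symbols as column
#'   names.
#' @param B number of equal-width bins (default `floor(sqrt(n_cells))`).
#' @param dpi_eps DPI tolerance; `0` is strict pruning, `Inf` disables
#'   pruning.
#' @return An undirected igraph graph over the genes with MI edge weights.
#' @export
aracne_network <- function(expr, B = max(2L, floor(sqrt(nrow(expr)))),
                           dpi_eps = 0) {
  expr <- as.matrix(unclass(expr))
  if (is.null(colnames(expr))) stop("expr needs gene symbols as column names")
  g <- ncol(expr)
  bins <- discretize_equal_width(expr, B)
  mi <- cpp_mi_matrix(bins, as.integer(attr(bins, "n_bins")))
  if (g < 3L) {
    warning("fewer than 3 genes: returning MI graph without DPI pruning")
    keep <- mi > 0
  } else {
    keep <- cpp_dpi_prune(mi, dpi_eps) & mi > 0
  }
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  gr <- igraph::make_empty_graph(n = g, directed = FALSE)
  gr <- igraph::set_vertex_attr(gr, "name", value = colnames(expr))
  if (nrow(idx) > 0) {
    gr <- igraph::add_edges(gr, rbind(idx[, 1], idx[, 2]))
    igraph::E(gr)$weight <- mi[idx]
  }
  gr
}

edge_keys <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  ee <- igraph::as_edgelist(g)
  paste(pmin(ee[, 1], ee[, 2]), pmax(ee[, 1], ee[, 2]), sep = "|")
}

#' Resampled GRN ensemble
#'
#' Runs `M` independent specimens: sample `N` cells, rank highly variable
#' genes (vst), intersect with the TF catalog, and infer an ARACNe network.
#' Appearance counts of every node and edge across specimens form the
#' support table of the significance layer.
#'
#' @param smoothed a [count_matrix] (typically [knn_smooth] output).
#' @param tfs character vector of transcription-factor symbols.
#' @param cfg a [resampling_config]; `cfg$M`, `cfg$N`, `cfg$n_hvg`,
#'   `cfg$n_bins`, `cfg$dpi_eps` and `cfg$seed` are used.
#' @return A list with `graphs` (length-`M` list of igraph specimens, `NULL`
#'   for skipped ones), `node_count`, `edge_count` (named integer vectors),
#'   `edge_mi_sum` (summed MI per edge, for consensus weights), `M_effective`
#'   and the resolved `cfg`.
#' @export
run_grn_ensemble <- function(smoothed, tfs, cfg) {
  stopifnot(is_count_matrix(smoothed), inherits(cfg, "resampling_config"))
  cfg <- resolve_config(cfg, nrow(smoothed))
  seeds <- derive_seeds(cfg$seed, cfg$M, stream = 1L)
  graphs <- vector("list", cfg$M)
  node_count <- integer(0)
  edge_count <- integer(0)
  edge_mi_sum <- numeric(0)
  skipped <- 0L
  for (m in seq_len(cfg$M)) {
    gm <- with_seed(seeds[m], {
      sub <- sample_cells(smoothed, cfg$N, replace = cfg$replace)
      hvg <- suppressWarnings(select_variable_genes(sub, cfg$n_hvg))
      tf_hvg <- intersect(hvg, tfs)
      if (length(tf_hvg) < 3L) NULL
      else aracne_network(unclass(sub)[, tf_hvg, drop = FALSE],
                          B = cfg$n_bins, dpi_eps = cfg$dpi_eps)
    })
    if (is.null(gm)) {
      skipped <- skipped + 1L
      next
    }
    graphs[[m]] <- gm
    nn <- igraph::V(gm)$name
    old_n <- node_count[nn]
    node_count[nn] <- ifelse(is.na(old_n), 0L, old_n) + 1L
    ek <- edge_keys(gm)
    if (length(ek)) {
      w <- igraph::E(gm)$weight
      old <- edge_count[ek]
      edge_count[ek] <- ifelse(is.na(old), 0L, old) + 1L
      oldw <- edge_mi_sum[ek]
      edge_mi_sum[ek] <- ifelse(is.na(oldw), 0, oldw) + w
    }
  }
  if (skipped > 0L)
    warning(sprintf("%d specimen(s) had fewer than 3 TF HVGs and were skipped",
                    skipped))
  list(graphs = graphs, node_count = node_count, edge_count = edge_count,
       edge_mi_sum = edge_mi_sum, M_effective = cfg$M - skipped, cfg = cfg)
}

#' Null rates from gene-name shuffling
#'
#' Estimates the per-specimen null appearance rates used by the Poisson
#' significance test. The node rate needs no resampling: under a uniform
#' name shuffle a given gene is called highly variable at rate
#' `n_hvg / n_genes`. The edge rate is estimated by `M_hat` cell resamples,
#' each shuffled `K` times: after shuffling, the specimen's network is built
#' from the HVG columns whose shuffled name is a TF, and the observed edges
#' are pooled over all `M_hat * K` specimens and divided by the number of
#' candidate TF pairs (pairs are exchangeable under the shuffle). Per-pair
#' rates are additionally tallied when `per_pair = TRUE`.
#'
#' @inheritParams run_grn_ensemble
#' @param per_pair also return per-pair null counts (rarely informative:
#'   a specific named pair almost never recurs among the shuffled specimens).
#' @return List with `lambda_node`, `lambda_edge`, `n_candidate_pairs`,
#'   `total_null_edges`, `n_specimens`, and optionally `pair_count`.
#' @export
run_null_ensemble <- function(smoothed, tfs, cfg, per_pair = FALSE) {
  stopifnot(is_count_matrix(smoothed), inherits(cfg, "resampling_config"))
  cfg <- resolve_config(cfg, nrow(smoothed))
  genes <- colnames(smoothed)
  tf_universe <- intersect(tfs, genes)
  n_tf <- length(tf_universe)
  C <- choose(n_tf, 2)
  lambda_node <- min(cfg$n_hvg, length(genes)) / length(genes)
  seeds <- derive_seeds(cfg$seed, cfg$M_hat, stream = 2L)
  total_edges <- 0
  pair_count <- if (per_pair) new.env(hash = TRUE) else NULL
  for (m in seq_len(cfg$M_hat)) {
    total_edges <- total_edges + with_seed(seeds[m], {
      sub <- sample_cells(smoothed, cfg$N, replace = cfg$replace)
      hvg <- suppressWarnings(select_variable_genes(sub, cfg$n_hvg))
      sub_edges <- 0
      for (k in seq_len(cfg$K)) {
        perm <- sample.int(length(genes))
        shuf_names <- genes[perm]
        names(shuf_names) <- genes
        cols <- hvg[shuf_names[hvg] %in% tf_universe]
        if (length(cols) < 2L) next
        expr <- unclass(sub)[, cols, drop = FALSE]
        colnames(expr) <- shuf_names[cols]
        gk <- if (ncol(expr) < 3L)
          suppressWarnings(aracne_network(expr, B = cfg$n_bins,
                                          dpi_eps = cfg$dpi_eps))
        else aracne_network(expr, B = cfg$n_bins, dpi_eps = cfg$dpi_eps)
        ne <- igraph::ecount(gk)
        if (per_pair && ne > 0) {
          for (key in edge_keys(gk)) {
            prev <- if (is.null(pair_count[[key]])) 0L else pair_count[[key]]
            pair_count[[key]] <- prev + 1L
          }
        }
        sub_edges <- sub_edges + ne
      }
      sub_edges
    })
  }
  n_specimens <- cfg$M_hat * cfg$K
  out <- list(lambda_node = lambda_node,
              lambda_edge = if (C > 0) total_edges / (n_specimens * C) else 0,
              n_candidate_pairs = C, total_null_edges = total_edges,
              n_specimens = n_specimens)
  if (per_pair)
    out$pair_count <- unlist(as.list(pair_count), use.names = TRUE)
  out
}

#' Poisson tail p-value for an appearance count
#'
#' `p = P(X >= count)` with `X ~ Poisson(lambda * M)`; a count of zero gives
#' `p = 1` exactly.
#'
#' @param count observed appearance count(s), nonnegative.
#' @param lam per-specimen null rate, nonnegative.
#' @param M number of specimens.
#' @return p-value(s) in (0, 1].
#' @export
poisson_tail_p <- function(count, lam, M) {
  if (any(count < 0) || any(lam < 0) || M < 1)
    stop("count and lam must be nonnegative, M >= 1")
  stats::ppois(count - 1, lambda = lam * M, lower.tail = FALSE)
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up FDR control valid under arbitrary dependence (harmonic-sum
#' inflation factor); thin wrapper over [stats::p.adjust].
#'
#' @param pvals vector of p-values in (0, 1].
#' @return Adjusted q-values (capped at 1).
#' @export
adjust_by <- function(pvals) stats::p.adjust(pvals, method = "BY")

#' Consensus network from a resampled ensemble
#'
#' Assigns each observed node and edge a Poisson p-value against its null
#' rate and a BY q-value (nodes and edges adjusted as separate families),
#' then keeps nodes with `q < q_threshold` and edges with `q < q_threshold`
#' whose both endpoints are retained. Edge weights are the mean MI over the
#' specimens containing the edge.
#'
#' @param ensemble result of [run_grn_ensemble].
#' @param null_rates result of [run_null_ensemble].
#' @param q_threshold significance cutoff; defaults to the ensemble's
#'   configured value.
#' @return A list of class `consensus_grn`: `graph` (igraph; empty, with a
#'   warning, when nothing is significant) and `support` (data.frame with
#'   columns type, id, count, lambda, p, q).
#' @export
consensus_grn <- function(ensemble, null_rates,
                          q_threshold = ensemble$cfg$q_threshold) {
  M <- ensemble$M_effective
  nodes <- names(ensemble$node_count)
  edges <- names(ensemble$edge_count)
  node_p <- if (length(nodes))
    poisson_tail_p(as.numeric(ensemble$node_count), null_rates$lambda_node, M)
  else numeric(0)
  node_q <- adjust_by(node_p)
  edge_lam <- rep(null_rates$lambda_edge, length(edges))
  if (!is.null(null_rates$pair_count)) {
    hit <- match(edges, names(null_rates$pair_count))
    per <- null_rates$pair_count[hit] / null_rates$n_specimens
    edge_lam <- ifelse(is.na(per), 0, per)
  }
  edge_p <- if (length(edges))
    poisson_tail_p(as.numeric(ensemble$edge_count), edge_lam, M)
  else numeric(0)
  edge_q <- adjust_by(edge_p)
  support <- rbind(
    data.frame(type = rep("node", length(nodes)), id = nodes,
               count = as.integer(ensemble$node_count),
               lambda = rep(null_rates$lambda_node, length(nodes)),
               p = node_p, q = node_q, stringsAsFactors = FALSE),
    data.frame(type = rep("edge", length(edges)), id = edges,
               count = as.integer(ensemble$edge_count),
               lambda = edge_lam, p = edge_p, q = edge_q,
               stringsAsFactors = FALSE))
  rownames(support) <- NULL
  keep_nodes <- nodes[node_q < q_threshold]
  keep_edge_keys <- edges[edge_q < q_threshold]
  if (length(keep_edge_keys)) {
    ends <- strsplit(keep_edge_keys, "|", fixed = TRUE)
    both_in <- vapply(ends, function(e) all(e %in% keep_nodes), logical(1))
    keep_edge_keys <- keep_edge_keys[both_in]
    ends <- ends[both_in]
  } else {
    ends <- list()
  }
  g <- igraph::make_empty_graph(n = length(keep_nodes), directed = FALSE)
  if (length(keep_nodes)) {
    g <- igraph::set_vertex_attr(g, "name", value = keep_nodes)
  } else {
    warning("consensus network is empty at q < ", q_threshold)
  }
  if (length(keep_edge_keys)) {
    em <- vapply(ends, function(e) match(e, keep_nodes), integer(2))
    g <- igraph::add_edges(g, em)
    igraph::E(g)$weight <- ensemble$edge_mi_sum[keep_edge_keys] /
      ensemble$edge_count[keep_edge_keys]
  }
  structure(list(graph = g, support = support, q_threshold = q_threshold),
            class = "consensus_grn")
}

#' @exportS3Method base::print
print.consensus_grn <- function(x, ...) {
  cat(sprintf("<consensus_grn> %d nodes, %d edges (q < %g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$q_threshold))
  invisible(x)
}
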