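#' Library-size normalization with log transform
#'
#' Scales each cell to `scale_factor` total counts and applies `log1p`; the
#' standard log-normalization used before PCA and for clump expression
#' profiles.
#'
#' @param counts a [count_matrix].
#' @param scale_factor target library size (default 1e4).
#' @return Numeric matrix, cells x genes.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  x <- unclass(counts)
  lib <- rowSums(x)
  lib[lib == 0] <- 1
  log1p(x / lib * scale_factor)
}

#' Partition cells into high-resolution clumps
#'
#' Builds the standard single-cell neighbour graph (log-normalization,
#' variable-gene selection, PCA, k-NN, shared-nearest-neighbour Jaccard
#' weights) and runs Louvain community detection over a grid of resolutions.
#' The returned partition uses the *highest* resolution whose smallest
#' community still has at least `ceiling(0.8 * k)` cells, so clump size
#' stays on the scale of the smoothing neighbourhood `k`; if no resolution
#' satisfies the floor, the lowest-resolution partition is returned with a
#' warning.
#'
#' @param counts a [count_matrix] (the original, unsmoothed counts).
#' @param k the smoothing neighbourhood size; sets the clump-size floor.
#' @param res_grid ascending vector of Louvain resolutions to try.
#' @param n_hvg,n_pcs,k_graph neighbour-graph construction parameters.
#' @param seed integer seed for the (randomized) Louvain refinement.
#' @return An object of class `clump_partition`: list with `labels` (named
#'   integer vector, cell -> clump), `resolution`, `min_size`, `n_clumps`.
#' @export
make_clumps <- function(counts, k, res_grid = c(0.5, 1, 2, 4, 6, 8, 10, 15, 20),
                        n_hvg = 2000L, n_pcs = 10L, k_graph = 20L, seed = 1L) {
  stopifnot(is_count_matrix(counts), length(res_grid) >= 1)
  if (is.unsorted(res_grid)) stop("res_grid must be ascending")
  floor_size <- ceiling(0.8 * k)
  expr <- lognormalize(counts)
  hvg <- suppressWarnings(select_variable_genes(counts,
                                                min(n_hvg, ncol(counts))))
  sub <- expr[, hvg, drop = FALSE]
  sub <- sub[, apply(sub, 2, stats::sd) > 0, drop = FALSE]
  sub <- scale(sub)
  attr(sub, "scaled:center") <- NULL
  attr(sub, "scaled:scale") <- NULL
  n_pcs <- min(n_pcs, dim(sub) - 1L)
  pcs <- with_seed(seed, stats::prcomp(sub, rank. = n_pcs, center = FALSE,
                                       scale. = FALSE)$x)
  gr <- snn_graph(pcs, k_graph = min(k_graph, nrow(pcs) - 1L))
  best <- NULL
  for (res in rev(sort(res_grid))) {
    memb <- with_seed(seed, igraph::membership(
      igraph::cluster_louvain(gr, resolution = res)))
    sizes <- table(memb)
    cand <- list(labels = stats::setNames(as.integer(memb), rownames(counts)),
                 resolution = res, min_size = as.integer(min(sizes)),
                 n_clumps = length(sizes))
    if (min(sizes) >= floor_size) {
      best <- cand
      break
    }
    best_low <- cand  # remembers the lowest resolution tried so far
  }
  if (is.null(best)) {
    warning("no resolution satisfies the clump-size floor ",
            floor_size, "; returning the lowest-resolution partition")
    best <- best_low
  }
  structure(c(best, list(size_floor = floor_size)), class = "clump_partition")
}

#' @exportS3Method base::print
print.clump_partition <- function(x, ...) {
  cat(sprintf("<clump_partition> %d clumps at resolution %g (min size %d, floor %d)\n",
              x$n_clumps, x$resolution, x$min_size, x$size_floor))
  invisible(x)
}

# Shared-nearest-neighbour graph with Jaccard weights (Seurat-style,
# prune threshold 1/15).
snn_graph <- function(pcs, k_graph = 20L, prune = 1 / 15) {
  n <- nrow(pcs)
  nn <- FNN::get.knn(pcs, k = k_graph)$nn.index
  i <- rep(seq_len(n), k_graph + 1L)
  j <- c(seq_len(n), as.vector(nn))  # self + neighbours
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(a)
  kk <- k_graph + 1L
  jac <- shared / (2 * kk - shared)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Mean expression profiles of clumps
#'
#' Averages the expression of the given genes over the cells of each clump;
#' the clustering substrate of the control-node stage.
#'
#' @param expr numeric matrix, cells x genes (typically [lognormalize]
#'   output on the original counts).
#' @param clumps a [make_clumps] partition over the same cells.
#' @param genes character vector of genes to profile (e.g. control nodes).
#' @return Numeric matrix of class `profile_matrix`, clumps x genes.
#' @export
clump_profiles <- function(expr, clumps, genes) {
  stopifnot(inherits(clumps, "clump_partition"))
  missing <- setdiff(genes, colnames(expr))
  if (length(missing))
    stop("genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  labs <- clumps$labels[rownames(expr)]
  if (anyNA(labs)) stop("cells missing from clump partition")
  sub <- expr[, genes, drop = FALSE]
  prof <- rowsum(sub, group = labs) / as.vector(table(labs))
  rownames(prof) <- paste0("clump", rownames(prof))
  class(prof) <- c("profile_matrix", "matrix", "array")
  prof
}
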