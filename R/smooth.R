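#' k-nearest-neighbour smoothing of counts on a 2-D embedding
#'
#' For each cell, finds the `k` nearest cells in the embedding (Euclidean
#' distance, the cell itself included, so `k = 1` is the identity) and
#' replaces the cell's expression by the truncated mean of the neighbourhood:
#' entry (c, g) becomes `floor(mean(counts[neighbours(c), g]))`. Truncation
#' keeps the smoothed matrix integral so it can feed the same count-based
#' pipeline as raw data.
#'
#' Distance ties at the k-th neighbour are broken by cell index order, so the
#' result is deterministic.
#'
#' @param counts a [count_matrix].
#' @param emb a [cell_embedding] with the same cell ids.
#' @param k neighbourhood size, `1 <= k <= n_cells`.
#' @return A [count_matrix] of the same shape.
#' @examples
#' cm <- count_matrix(matrix(c(0, 2, 3, 1), 2, 2), c("a", "b"), c("g1", "g2"))
#' em <- cell_embedding(matrix(c(0, 1, 0, 0), 2, 2), c("a", "b"))
#' knn_smooth(cm, em, k = 2)  # both cells become floor(colMeans)
#' @export
knn_smooth <- function(counts, emb, k) {
  stopifnot(is_count_matrix(counts))
  n <- nrow(counts)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be between 1 and the number of cells")
  emb <- align_embedding(emb, counts)
  if (k == 1L) return(counts)
  # FNN returns neighbours ordered by distance; ties beyond that order are
  # broken deterministically below by re-sorting candidate indices.
  nn <- FNN::get.knnx(unclass(emb), unclass(emb), k = k, algorithm = "kd_tree")
  idx <- nn$nn.index
  # Resolve ties at the k-th neighbour by cell index: for each cell, if the
  # k-th distance is shared by cells outside the returned set, prefer the
  # smallest indices among all cells at distance <= the k-th distance.
  dk <- nn$nn.dist[, k]
  # Exact tie handling only matters for degenerate embeddings; detect rows
  # where the k-th and (k+1)-th distances coincide.
  if (k < n) {
    nn1 <- FNN::get.knnx(unclass(emb), unclass(emb), k = min(n, k + 1L),
                         algorithm = "kd_tree")
    tied <- which(abs(nn1$nn.dist[, k + 1L] - dk) <= 1e-12)
    for (c_i in tied) {
      d_all <- sqrt(colSums((t(emb) - emb[c_i, ])^2))
      eligible <- which(d_all <= dk[c_i] + 1e-12)
      # self always belongs to the neighbourhood; remaining slots by index
      others <- setdiff(sort(eligible), c_i)
      idx[c_i, ] <- c(c_i, others[seq_len(k - 1L)])
    }
  }
  sm <- matrix(0, n, ncol(counts))
  base <- unclass(counts)
  for (j in seq_len(k)) sm <- sm + base[idx[, j], , drop = FALSE]
  sm <- floor(sm / k)
  count_matrix(sm, cell_ids = rownames(counts), gene_ids = colnames(counts))
}
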