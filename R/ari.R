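#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two partitions of the
#' same members, computed from the contingency table:
#' `ARI = (sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)` and
#' `max = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`. Identical partitions give
#' 1; independent partitions give ~0; degenerate cases where `max = E`
#' return 0 by convention.
#'
#' @param a,b partition label vectors over the same members. If both are
#'   named, members are matched by name; otherwise the vectors must have
#'   equal length and positional correspondence.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("partitions are over different member sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("partitions are over different member sets")
  }
  if (anyNA(a) || anyNA(b)) stop("partition labels contain NA")
  n <- length(a)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(0)
  (sum_ij - expected) / (maximum - expected)
}

#' Expand a clump-level clustering to cells
#'
#' Each cell inherits the cluster label of its clump.
#'
#' @param clumps a [make_clumps] partition.
#' @param clustering named integer vector, clump id (`"clump<i>"` or bare
#'   index) -> cluster label, covering every clump.
#' @return Named integer vector, cell -> cluster label.
#' @export
expand_to_cells <- function(clumps, clustering) {
  stopifnot(inherits(clumps, "clump_partition"))
  keys <- names(clustering)
  if (is.null(keys)) stop("clustering must be named by clump id")
  keys <- sub("^clump", "", keys)
  lab_of <- stats::setNames(as.integer(clustering), keys)
  cell_clump <- as.character(clumps$labels)
  if (!all(unique(cell_clump) %in% keys))
    stop("clustering does not label every clump")
  out <- lab_of[cell_clump]
  if (anyNA(out)) stop("clustering does not label every clump")
  names(out) <- names(clumps$labels)
  out
}
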