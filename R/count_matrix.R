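#' Cells-by-genes count matrix
#'
#' Light container for a nonnegative integer expression matrix with cells as
#' rows and genes as columns. All pipeline stages operate on this type; 10x
#' style genes-by-cells input is transposed at read time.
#'
#' @param values numeric matrix (or Matrix) of nonnegative integers,
#'   cells in rows, genes in columns.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#' @param gene_ids character vector of unique gene symbols, one per column.
#' @return An object of class `count_matrix`: the integer matrix with
#'   `dimnames = list(cell_ids, gene_ids)`.
#' @examples
#' m <- count_matrix(matrix(0:3, 2, 2), c("c1", "c2"), c("g1", "g2"))
#' dim(m)
#' @export
count_matrix <- function(values, cell_ids = rownames(values),
                         gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("length(cell_ids) must equal nrow(values)")
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) must equal ncol(values)")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyNA(values)) stop("counts contain NA")
  if (any(values < 0)) stop("counts must be nonnegative")
  if (any(values != floor(values))) stop("counts must be integral")
  storage.mode(values) <- "double"  # keeps large counts safe; integral by check
  dimnames(values) <- list(cell_ids, gene_ids)
  class(values) <- c("count_matrix", "matrix", "array")
  values
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes, total counts %g\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Test or coerce count_matrix
#' @param x object
#' @return `is_count_matrix` returns a logical; `as_count_matrix` a
#'   `count_matrix`.
#' @export
is_count_matrix <- function(x) inherits(x, "count_matrix")

#' @rdname is_count_matrix
#' @export
as_count_matrix <- function(x) {
  if (is_count_matrix(x)) return(x)
  count_matrix(as.matrix(x))
}

#' 2-D per-cell embedding
#'
#' Coordinates of each cell in a two-dimensional embedding (typically UMAP),
#' aligned to a [count_matrix] by cell id.
#'
#' @param coords numeric matrix, cells x 2, finite.
#' @param cell_ids character vector of unique cell ids, one per row.
#' @return A numeric matrix of class `cell_embedding` with rownames
#'   `cell_ids`.
#' @export
cell_embedding <- function(coords, cell_ids = rownames(coords)) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("embedding must have exactly 2 columns")
  if (!all(is.finite(coords))) stop("embedding coordinates must be finite")
  if (is.null(cell_ids)) stop("embedding requires cell ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids in embedding")
  storage.mode(coords) <- "double"
  rownames(coords) <- as.character(cell_ids)
  colnames(coords) <- c("dim1", "dim2")
  class(coords) <- c("cell_embedding", "matrix", "array")
  coords
}

# Align an embedding to the cell order of a count matrix; errors if the id
# sets differ.
align_embedding <- function(emb, counts) {
  ids <- rownames(counts)
  if (!setequal(rownames(emb), ids))
    stop("embedding cell ids do not match count matrix cell ids")
  emb2 <- emb[ids, , drop = FALSE]
  class(emb2) <- class(emb)
  emb2
}

#' Resampling and significance configuration
#'
#' Bundles the tuning parameters of the resampling pipeline. Defaults follow
#' the published procedure: `M = 100` network resamples, `M_hat = 1000` null
#' resamples each shuffled `K = 100` times (1e5 shuffled specimens),
#' `n_hvg = 2000` variable genes, and a significance cutoff `q_threshold =
#' 1e-5`. `N` defaults to one third of the cells, capped at 20000.
#'
#' @param k integer, number of nearest neighbours for smoothing (and the
#'   clump-size scale downstream).
#' @param N integer, cells per resample; default `min(ceiling(n/3), 20000)`
#'   resolved against the data when the pipeline runs.
#' @param M integer, number of resampled networks.
#' @param M_hat integer, number of null resamples.
#' @param K integer, gene-name shuffles per null resample.
#' @param n_hvg integer, number of highly variable genes per specimen.
#' @param q_threshold numeric in (0,1), BY q-value cutoff.
#' @param n_bins integer or NULL; equal-width bins for MI estimation.
#'   `NULL` means `floor(sqrt(N))` resolved at run time.
#' @param dpi_eps numeric >= 0, DPI pruning tolerance (0 = strict).
#' @param replace logical, resample cells with replacement (default FALSE:
#'   subsampling without replacement).
#' @param seed integer master seed; all specimen-level streams derive from it.
#' @return A list of class `resampling_config`.
#' @export
resampling_config <- function(k = 10L, N = NULL, M = 100L, M_hat = 1000L,
                              K = 100L, n_hvg = 2000L, q_threshold = 1e-5,
                              n_bins = NULL, dpi_eps = 0, replace = FALSE,
                              seed = 1L) {
  stopifnot(k >= 1, M >= 1, M_hat >= 1, K >= 1, n_hvg >= 1,
            q_threshold > 0, q_threshold < 1, dpi_eps >= 0)
  if (!is.null(N)) stopifnot(N >= 1)
  if (!is.null(n_bins)) stopifnot(n_bins >= 2)
  structure(list(k = as.integer(k), N = if (is.null(N)) NULL else as.integer(N),
                 M = as.integer(M), M_hat = as.integer(M_hat),
                 K = as.integer(K), n_hvg = as.integer(n_hvg),
                 q_threshold = q_threshold,
                 n_bins = if (is.null(n_bins)) NULL else as.integer(n_bins),
                 dpi_eps = dpi_eps, replace = isTRUE(replace),
                 seed = as.integer(seed)),
            class = "resampling_config")
}

# Resolve data-dependent defaults (N, n_bins) against an actual matrix.
resolve_config <- function(cfg, n_cells) {
  if (is.null(cfg$N)) cfg$N <- as.integer(min(ceiling(n_cells / 3), 20000L))
  if (cfg$N > n_cells) stop("N exceeds the number of cells")
  if (is.null(cfg$n_bins)) cfg$n_bins <- max(2L, as.integer(floor(sqrt(cfg$N))))
  cfg
}

# Derive independent per-specimen seeds from the master seed so the M and
# M_hat loops are order-independent. Kept below 2^31.
derive_seeds <- function(seed, n, stream = 0L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed((as.integer(seed) + 1000003L * as.integer(stream)) %% 2147483647L)
  sample.int(2147483646L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run a thunk under a local seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}
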