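#' Read a count matrix
#'
#' Reads cells-by-genes integer counts from either a 10x-style MatrixMarket
#' directory (`matrix.mtx` + `features.tsv`/`genes.tsv` + `barcodes.tsv`,
#' optionally gzipped) or a dense delimited file with gene columns and a
#' first column (or row names) of cell ids. MatrixMarket input follows the
#' 10x convention of genes in rows and is transposed so that cells are rows.
#'
#' @param path file (csv/tsv) or directory (mtx_dir) to read.
#' @param format one of `"mtx_dir"`, `"csv"`, `"tsv"`; default guesses from
#'   `path` (directory -> mtx_dir, extension otherwise).
#' @return A [count_matrix].
#' @export
read_counts <- function(path, format = c("auto", "mtx_dir", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx_dir"
      else if (grepl("\\.csv(\\.gz)?$", path)) "csv" else "tsv"
  }
  if (format == "mtx_dir") return(read_counts_mtx(path))
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 1L) stop("empty table: ", path)
  if (is.character(df[[1]]) || is.factor(df[[1]])) {
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  } else {
    ids <- rownames(df)
  }
  vals <- as.matrix(df)
  if (!is.numeric(vals)) stop("non-numeric entries in count table")
  count_matrix(vals, cell_ids = ids, gene_ids = colnames(df))
}

first_existing <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  stop("none of ", paste(names, collapse = ", "), " found in ", dir)
}

read_counts_mtx <- function(dir) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  mtx <- first_existing(dir, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- first_existing(dir, c("features.tsv", "features.tsv.gz",
                                "genes.tsv", "genes.tsv.gz"))
  barc <- first_existing(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  m <- Matrix::readMM(mtx)
  features <- utils::read.table(feat, sep = "\t", stringsAsFactors = FALSE)
  barcodes <- utils::read.table(barc, sep = "\t", stringsAsFactors = FALSE)
  gene_ids <- if (ncol(features) >= 2L) features[[2]] else features[[1]]
  if (nrow(features) != nrow(m) || nrow(barcodes) != ncol(m))
    stop("feature/barcode tables do not match matrix dimensions")
  dense <- as.matrix(Matrix::t(m))  # 10x stores genes x cells
  count_matrix(dense, cell_ids = barcodes[[1]], gene_ids = gene_ids)
}

#' Read a 2-D embedding
#'
#' Expects a delimited table with a cell-id column followed by two coordinate
#' columns (header optional but recommended).
#'
#' @param path csv/tsv file.
#' @param sep field separator; guessed from the extension by default.
#' @return A [cell_embedding].
#' @export
read_embedding <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("embedding table needs id + 2 coordinate columns")
  cell_embedding(as.matrix(df[, 2:3]), cell_ids = df[[1]])
}

#' Read a gene list (transcription-factor catalog)
#'
#' One symbol per line; blank lines and `#` comments are ignored; surrounding
#' whitespace is stripped and duplicates dropped.
#'
#' @param path text file.
#' @return Character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  syms <- unique(lines[nzchar(lines)])
  if (length(syms) == 0L) stop("empty gene list: ", path)
  syms
}

#' Write / read a weighted undirected network
#'
#' `edge_tsv` is a 3-column table `gene_a`, `gene_b`, `weight` plus a
#' `#vertices:` header line preserving isolated vertices; `graphml` delegates
#' to igraph. Round-trips are lossless for the vertex set, edge set and
#' weights.
#'
#' @param g an igraph undirected graph with a `weight` edge attribute.
#' @param path output file.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return `write_graph_file` returns `path` invisibly; `read_graph_file`
#'   returns an igraph graph.
#' @export
write_graph_file <- function(g, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(igraph::is_igraph(g))
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#vertices: ",
                    paste(igraph::V(g)$name, collapse = "\t")), con)
  writeLines("gene_a\tgene_b\tweight", con)
  if (igraph::ecount(g) > 0) {
    ee <- igraph::as_data_frame(g, what = "edges")
    w <- if ("weight" %in% names(ee)) ee$weight else rep(1, nrow(ee))
    writeLines(sprintf("%s\t%s\t%.17g", ee$from, ee$to, w), con)
  }
  invisible(path)
}

#' @rdname write_graph_file
#' @export
read_graph_file <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(igraph::as_undirected(g, mode = "collapse"))
  }
  lines <- readLines(path)
  stopifnot(length(lines) >= 2L, startsWith(lines[1], "#vertices:"))
  vline <- sub("^#vertices:[ ]?", "", lines[1])
  verts <- if (nzchar(vline)) strsplit(vline, "\t", fixed = TRUE)[[1]]
           else character(0)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (length(lines) > 2L) {
    df <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    g <- igraph::add_edges(g, rbind(match(df$gene_a, verts),
                                    match(df$gene_b, verts)))
    igraph::E(g)$weight <- df$weight
  }
  g
}

#' Write a run-metadata sidecar
#'
#' Records the configuration, seed and package version next to an artifact so
#' a run can be reproduced from its outputs alone.
#'
#' @param path artifact path; metadata is written to `paste0(path, ".meta.json")`.
#' @param cfg a [resampling_config] (or any list of parameters).
#' @param extra named list of extra fields to record.
#' @return The sidecar path, invisibly.
#' @export
write_run_meta <- function(path, cfg, extra = list()) {
  meta <- c(list(artifact = basename(path),
                 package = "grnboot",
                 version = as.character(utils::packageVersion("grnboot")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 config = unclass(cfg)),
            extra)
  out <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, out, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(out)
}
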