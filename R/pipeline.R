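#' Run the full resampling pipeline
#'
#' Orchestrates smoothing, the resampled GRN ensemble with its shuffled-name
#' null, consensus-network construction, control-node computation, clump
#' generation and clump clustering.
#'
#' Two modes mirror the two published procedures:
#' * `auto = FALSE` (the original procedure): a single minimum dominating
#'   set of the consensus network supplies the profile genes, and the clump
#'   dendrogram is cut at the user-chosen `k_clusters`.
#' * `auto = TRUE` (the automated procedure): the enumerated critical and
#'   intermittent control nodes supply the profile genes, multiscale
#'   bootstrap assigns AU support to the dendrogram, and the number of
#'   clusters is chosen automatically ([choose_k]).
#'
#' @param counts raw [count_matrix].
#' @param embedding [cell_embedding] aligned to `counts`.
#' @param tfs transcription-factor catalog (character).
#' @param cfg a [resampling_config].
#' @param auto automated mode (control nodes + auto-k) or manual mode
#'   (single MDS + `k_clusters`).
#' @param k_clusters number of clusters for manual mode.
#' @param res_grid Louvain resolution grid for [make_clumps].
#' @param n_solutions MDS enumeration depth (automated mode).
#' @param scales,bootstrap_B,alpha multiscale-bootstrap settings
#'   (automated mode).
#' @param skip_smoothing treat `counts` as already smoothed.
#' @return An object of class `grnboot_run`: list with `smoothed`,
#'   `ensemble`, `null_rates`, `consensus`, `control` (gene set; in
#'   automated mode also the full `control_set`), `clumps`, `profiles`,
#'   `tree`, `k`, `clump_clusters`, `cell_clusters`, `cfg` and (automated
#'   mode) `bootstrap` and `confident`.
#' @export
run_pipeline <- function(counts, embedding, tfs, cfg, auto = FALSE,
                         k_clusters = NULL,
                         res_grid = c(0.5, 1, 2, 4, 6, 8, 10, 15, 20),
                         n_solutions = 15L,
                         scales = seq(0.5, 1.4, by = 0.1),
                         bootstrap_B = 1000L, alpha = 0.05,
                         skip_smoothing = FALSE) {
  stopifnot(is_count_matrix(counts), inherits(cfg, "resampling_config"))
  if (!auto && is.null(k_clusters))
    stop("manual mode requires k_clusters")
  cfg <- resolve_config(cfg, nrow(counts))
  stage_seeds <- derive_seeds(cfg$seed, 2L, stream = 9L)

  smoothed <- if (skip_smoothing) counts
              else knn_smooth(counts, embedding, cfg$k)
  ensemble <- run_grn_ensemble(smoothed, tfs, cfg)
  null_rates <- run_null_ensemble(smoothed, tfs, cfg)
  consensus <- consensus_grn(ensemble, null_rates)
  if (igraph::vcount(consensus$graph) == 0L)
    stop("consensus network is empty; nothing to dominate or cluster")

  if (auto) {
    cs <- enumerate_optimal_mds(consensus$graph, n_solutions = n_solutions)
    control_genes <- sort(c(cs$critical, cs$intermittent))
  } else {
    cs <- NULL
    control_genes <- sort(min_dominating_set(consensus$graph))
  }

  clumps <- make_clumps(counts, k = cfg$k, res_grid = res_grid,
                        seed = stage_seeds[1])
  expr <- lognormalize(counts)
  profiles <- clump_profiles(expr, clumps, control_genes)
  tree <- ward_tree(profiles)

  if (auto) {
    ms <- multiscale_bootstrap(profiles, tree, scales = scales,
                               B = bootstrap_B, seed = stage_seeds[2])
    confident <- pick_confident(ms, alpha = alpha)
    k <- choose_k(ms, confident)
  } else {
    ms <- NULL
    confident <- NULL
    k <- as.integer(k_clusters)
  }
  clump_clusters <- cut_clusters(tree, k)
  cell_clusters <- expand_to_cells(clumps, clump_clusters)

  structure(list(smoothed = smoothed, ensemble = ensemble,
                 null_rates = null_rates, consensus = consensus,
                 control = control_genes, control_set = cs,
                 clumps = clumps, profiles = profiles, tree = tree,
                 bootstrap = ms, confident = confident, k = as.integer(k),
                 clump_clusters = clump_clusters,
                 cell_clusters = cell_clusters, cfg = cfg, auto = auto),
            class = "grnboot_run")
}

#' @exportS3Method base::print
print.grnboot_run <- function(x, ...) {
  cat(sprintf(
    "<grnboot_run> %s mode\n  consensus: %d nodes, %d edges\n  control genes: %d\n  clumps: %d -> %d clusters (k %s)\n",
    if (x$auto) "automated" else "manual",
    igraph::vcount(x$consensus$graph), igraph::ecount(x$consensus$graph),
    length(x$control), x$clumps$n_clumps, x$k,
    if (x$auto) "chosen automatically" else "set manually"))
  invisible(x)
}

#' Write the artifacts of a pipeline run
#'
#' Writes the support table, consensus network (GraphML and edge TSV),
#' control-node table, clump profile matrix, cell cluster assignments and,
#' in automated mode, the AU-annotated dendrogram in Newick form. Every
#' artifact gets a JSON metadata sidecar recording the configuration and
#' seed, so a run is reproducible from its outputs.
#'
#' @param run a [run_pipeline] result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(run, out_dir) {
  stopifnot(inherits(run, "grnboot_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  utils::write.table(run$consensus$support, pth("support.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_graph_file(run$consensus$graph, pth("grn.graphml"), "graphml")
  write_graph_file(run$consensus$graph, pth("grn_edges.tsv"), "edge_tsv")

  ctrl <- if (!is.null(run$control_set)) {
    cs <- run$control_set
    counts <- rep(0L, length(run$control))
    names(counts) <- run$control
    hits <- cs$solution_count[intersect(names(cs$solution_count), run$control)]
    counts[names(hits)] <- as.integer(hits)
    data.frame(gene = run$control,
               class = ifelse(run$control %in% cs$critical,
                              "critical", "intermittent"),
               n_solutions_containing = counts,
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(gene = run$control, class = "mds",
               n_solutions_containing = 1L, stringsAsFactors = FALSE)
  }
  utils::write.table(ctrl, pth("control_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  utils::write.csv(as.matrix(run$profiles), pth("clump_profiles.csv"))
  clusters <- data.frame(cell_id = names(run$cell_clusters),
                         clump = run$clumps$labels[names(run$cell_clusters)],
                         cluster = as.integer(run$cell_clusters),
                         stringsAsFactors = FALSE)
  utils::write.table(clusters, pth("clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(run$bootstrap))
    write_tree_newick(run$bootstrap, pth("tree_au.nwk"))
  write_run_meta(pth("run"), run$cfg,
                 extra = list(auto = run$auto, k = run$k,
                              n_control = length(run$control)))
  invisible(out_dir)
}

#' Export an AU-annotated dendrogram as Newick
#'
#' Internal nodes carry their AU value (rounded to 3 digits) as node labels.
#'
#' @param tree a [multiscale_bootstrap] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  hc <- tree$hclust
  n <- length(hc$order)
  lab <- if (!is.null(hc$labels)) hc$labels else as.character(seq_len(n))
  # recursive Newick over the merge matrix; branch lengths from heights
  node_str <- function(node, parent_h) {
    h <- hc$height[node]
    kids <- vapply(hc$merge[node, ], function(child) {
      if (child < 0) sprintf("%s:%.6g", lab[-child], h)
      else node_str(child, h)
    }, character(1))
    sprintf("(%s)%.3f:%.6g", paste(kids, collapse = ","),
            tree$au[node], max(parent_h - h, 0))
  }
  writeLines(paste0(node_str(n - 1L, hc$height[n - 1L]), ";"), path)
  invisible(path)
}
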