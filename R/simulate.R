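#' Simulate a single-cell dataset with planted regulatory structure
#'
#' Generates negative-binomial counts whose statistical shape mirrors the
#' real droplet datasets the pipeline targets: discrete cell types, each
#' with its own program of active regulator TFs, regulator-to-target
#' transmission that plants detectable mutual information, an iid NB
#' background, and a 2-D embedding of type-separated Gaussian blobs.
#'
#' Each regulator's latent log-activity is its baseline, plus `effect_size`
#' in the cell type where it is active, plus a smooth random activity field
#' over the embedding (random Fourier features at the blob length-scale,
#' marginal SD `activity_sd`; fields of different regulators are mutually
#' uncorrelated). Continuous cell-state variation in real data is smooth
#' across the map -- that is the premise of k-NN smoothing -- so the field
#' survives smoothing while iid noise does not. Each planted target reads
#' its regulator's centred activity (type activation plus field) with
#' `N(0, noise_sd)` iid noise on top. Regulators are highly expressed
#' (clean NB readout of their own activity) whereas targets sit at ordinary
#' expression levels with extra transmission noise, so the regulator-target
#' edge is the strongest edge of every triangle it takes part in -- the
#' configuration the DPI step is designed to resolve. Counts are NB with a
#' common dispersion. Setting `effect_size = 0` removes the type structure;
#' letting `noise_sd` grow drowns the planted mutual information.
#'
#' @param n_cells,n_genes dataset dimensions.
#' @param n_types number of cell types (`>= 2`).
#' @param n_regulators regulators *per type*.
#' @param targets_per_regulator planted targets per regulator.
#' @param nb_dispersion NB dispersion (variance `mu + dispersion * mu^2`).
#' @param effect_size log-scale activation of a regulator in its own type.
#' @param noise_sd log-scale iid noise on target transmission.
#' @param activity_sd marginal SD of the within-type activity gradient.
#' @param regulator_mean baseline count mean of regulator genes.
#' @param tf_decoy_frac fraction of genes added to the TF catalog as inert
#'   decoys, so the TF-restriction step is exercised.
#' @param embedding_sep,embedding_sd type-blob geometry of the 2-D embedding.
#' @param seed integer seed; the output is fully determined by it.
#' @return List with `counts` ([count_matrix]), `embedding`
#'   ([cell_embedding]), `tfs` (character), and `truth` (list: `cell_type`,
#'   `regulators` per type, `edges` data.frame of planted regulator-target
#'   pairs, `params`).
#' @export
simulate_dataset <- function(n_cells = 1500L, n_genes = 1000L, n_types = 3L,
                             n_regulators = 5L, targets_per_regulator = 10L,
                             nb_dispersion = 0.5, effect_size = 2,
                             noise_sd = 0.8, activity_sd = 0.7,
                             regulator_mean = 8, tf_decoy_frac = 0.2,
                             embedding_sep = 10, embedding_sd = 1,
                             seed = 1L) {
  stopifnot(n_types >= 2, n_regulators >= 1, targets_per_regulator >= 1)
  n_reg <- n_types * n_regulators
  n_tgt <- n_reg * targets_per_regulator
  if (n_reg + n_tgt > n_genes)
    stop("infeasible gene budget: regulators and targets exceed n_genes")
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    reg_genes <- genes[seq_len(n_reg)]
    tgt_genes <- genes[n_reg + seq_len(n_tgt)]
    bg_genes <- genes[-seq_len(n_reg + n_tgt)]
    reg_type <- rep(seq_len(n_types), each = n_regulators)
    tgt_reg <- rep(seq_len(n_reg), each = targets_per_regulator)

    cell_type <- sample(rep_len(seq_len(n_types), n_cells))
    # background spans the usual dynamic range so the mean-variance trend is
    # anchored at every expression level; targets sit at moderate levels
    base_logmu <- stats::runif(n_genes, log(0.1), log(50))
    names(base_logmu) <- genes
    base_logmu[tgt_genes] <- stats::runif(n_tgt, log(0.5), log(4))
    base_logmu[reg_genes] <- log(regulator_mean)

    # embedding first: within-type offsets drive the activity gradient
    theta <- 2 * pi * (cell_type - 1) / n_types
    offsets <- matrix(stats::rnorm(2 * n_cells, 0, embedding_sd), n_cells, 2)
    emb <- cbind(embedding_sep * cos(theta), embedding_sep * sin(theta)) +
      offsets
    cells <- sprintf("cell%04d", seq_len(n_cells))
    embedding <- cell_embedding(emb, cell_ids = cells)

    # regulator latent activity: baseline + type activation + a smooth
    # random activity field over the embedding (random Fourier features at
    # the blob length-scale, two components per regulator). Fields of
    # different regulators are mutually uncorrelated but smooth at the k-NN
    # scale, so the planted regulator-target coupling survives smoothing
    # while cross-regulator couplings stay weak. Targets read the field (the
    # continuous activity state), so the planted edge is the only strong
    # cross-gene dependency beyond the type programs on the regulators.
    n_feat <- 2L
    freq <- array(stats::rnorm(2 * n_feat * n_reg, 0, 1 / embedding_sd),
                  c(2, n_feat, n_reg))
    phase <- matrix(stats::runif(n_feat * n_reg, 0, 2 * pi), n_feat, n_reg)
    grad <- matrix(0, n_cells, n_reg)
    for (r in seq_len(n_reg)) {
      ph <- emb %*% freq[, , r]  # absolute position: patterns differ by type
      grad[, r] <- activity_sd * sqrt(2 / n_feat) *
        rowSums(cos(sweep(ph, 2, phase[, r], "+")))
    }
    act <- matrix(base_logmu[reg_genes], n_cells, n_reg, byrow = TRUE)
    act <- act + effect_size * outer(cell_type, reg_type, "==")
    act <- act + grad

    logmu <- matrix(base_logmu, n_cells, n_genes, byrow = TRUE)
    logmu[, seq_len(n_reg)] <- act
    transmitted <- sweep(act, 2, base_logmu[reg_genes])  # activation + field
    logmu[, n_reg + seq_len(n_tgt)] <-
      matrix(base_logmu[tgt_genes], n_cells, n_tgt, byrow = TRUE) +
      transmitted[, tgt_reg, drop = FALSE] +
      matrix(stats::rnorm(n_cells * n_tgt, 0, noise_sd), n_cells, n_tgt)
    logmu <- pmin(logmu, log(1e4))

    counts <- matrix(stats::rnbinom(n_cells * n_genes,
                                    mu = exp(logmu), size = 1 / nb_dispersion),
                     n_cells, n_genes)
    cm <- count_matrix(counts, cell_ids = cells, gene_ids = genes)

    n_decoy <- round(tf_decoy_frac * n_genes)
    decoys <- sample(bg_genes, min(n_decoy, length(bg_genes)))
    tfs <- sort(unique(c(reg_genes, tgt_genes, decoys)))

    truth <- list(
      cell_type = stats::setNames(cell_type, cells),
      regulators = split(reg_genes, reg_type),
      edges = data.frame(regulator = reg_genes[tgt_reg], target = tgt_genes,
                         stringsAsFactors = FALSE),
      params = list(n_cells = n_cells, n_genes = n_genes, n_types = n_types,
                    n_regulators = n_regulators,
                    targets_per_regulator = targets_per_regulator,
                    nb_dispersion = nb_dispersion, effect_size = effect_size,
                    noise_sd = noise_sd, activity_sd = activity_sd,
                    regulator_mean = regulator_mean, seed = seed))
    list(counts = cm, embedding = embedding, tfs = tfs, truth = truth)
  })
}

#' Simulate a structureless (iid negative-binomial) dataset
#'
#' Null fixture: every gene is independent NB noise, the embedding is a
#' single Gaussian blob, and the TF catalog is a random subset of genes.
#' Used to verify that the significance layer reports nothing.
#'
#' @inheritParams simulate_dataset
#' @param tf_frac fraction of genes declared TFs.
#' @return List with `counts`, `embedding`, `tfs`.
#' @export
simulate_null_dataset <- function(n_cells = 600L, n_genes = 300L,
                                  nb_dispersion = 0.5, tf_frac = 0.2,
                                  seed = 1L) {
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    cells <- sprintf("cell%04d", seq_len(n_cells))
    base_logmu <- stats::runif(n_genes, log(0.2), log(2))
    counts <- matrix(stats::rnbinom(n_cells * n_genes,
                                    mu = exp(rep(base_logmu, each = n_cells)),
                                    size = 1 / nb_dispersion),
                     n_cells, n_genes)
    cm <- count_matrix(counts, cell_ids = cells, gene_ids = genes)
    emb <- cell_embedding(matrix(stats::rnorm(2 * n_cells, 0, 3), n_cells, 2),
                          cell_ids = cells)
    tfs <- sort(sample(genes, round(tf_frac * n_genes)))
    list(counts = cm, embedding = emb, tfs = tfs)
  })
}

#' Simulate an Erdos-Renyi random graph
#'
#' `G(n, p)` with unit edge weights and named vertices; used to exercise the
#' dominating-set solvers.
#'
#' @param n number of vertices.
#' @param p edge probability in `[0, 1]`.
#' @param seed integer seed.
#' @return An undirected igraph graph.
#' @export
simulate_random_graph <- function(n, p, seed = 1L) {
  stopifnot(p >= 0, p <= 1)
  with_seed(seed, {
    g <- igraph::sample_gnp(n, p, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name",
                                 value = sprintf("v%02d", seq_len(n)))
    if (igraph::ecount(g) > 0) igraph::E(g)$weight <- 1
    g
  })
}

#' Simulate a block-structured profile matrix
#'
#' Clumps belong to `k_blocks` blocks; each block has its own mean vector
#' with between-block separation `sep` (in units of the unit within-block
#' noise SD). Used to validate the automatic choice of the number of
#' clusters.
#'
#' @param n_clumps,n_genes matrix dimensions.
#' @param k_blocks number of planted blocks (`<= n_clumps`).
#' @param sep block separation in SD units.
#' @param seed integer seed.
#' @return List with `profiles` (clumps x genes matrix) and `labels`
#'   (integer block membership).
#' @export
simulate_profile_blocks <- function(n_clumps, n_genes, k_blocks, sep,
                                    seed = 1L) {
  stopifnot(k_blocks <= n_clumps, k_blocks >= 1)
  with_seed(seed, {
    labels <- sort(rep_len(seq_len(k_blocks), n_clumps))
    centers <- matrix(stats::rnorm(k_blocks * n_genes, 0, sep),
                      k_blocks, n_genes)
    prof <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_clumps * n_genes), n_clumps, n_genes)
    dimnames(prof) <- list(paste0("clump", seq_len(n_clumps)),
                           sprintf("g%03d", seq_len(n_genes)))
    class(prof) <- c("profile_matrix", "matrix", "array")
    list(profiles = prof, labels = stats::setNames(labels, rownames(prof)))
  })
}
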