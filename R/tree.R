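#' Ward dendrogram on correlation dissimilarity
#'
#' Clusters clump profiles hierarchically with Ward's criterion on the
#' dissimilarity `d(i, j) = 1 - Pearson(row_i, row_j)`. The default uses the
#' squared-dissimilarity Ward update (`hclust` method `"ward.D2"`, the
#' modern form); the classic unsquared recurrence is available for
#' cross-checking.
#'
#' @param profiles a [clump_profiles] matrix (rows are clumps).
#' @param variant `"ward.D2"` (default) or `"ward.D"`.
#' @return An `hclust` tree over the profile rows.
#' @export
ward_tree <- function(profiles, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  if (nrow(profiles) < 2L) stop("need at least 2 clumps")
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance profile row(s): ",
         paste(rownames(profiles)[sds == 0], collapse = ", "),
         "; drop or merge these clumps before clustering")
  d <- stats::as.dist(1 - stats::cor(t(profiles)))
  stats::hclust(d, method = variant)
}

#' Cut a dendrogram into k clusters
#'
#' @param tree an `hclust` tree (or a [multiscale_bootstrap] result).
#' @param k number of clusters, `1 <= k <= n`.
#' @return Named integer vector, member -> cluster label in `1..k`.
#' @export
cut_clusters <- function(tree, k) {
  hc <- as_hclust(tree)
  n <- length(hc$order)
  if (k < 1 || k > n) stop("k out of range")
  stats::cutree(hc, k = k)
}

as_hclust <- function(tree) {
  if (inherits(tree, "hclust")) tree
  else if (inherits(tree, "cluster_tree")) tree$hclust
  else stop("not a tree")
}

# Leaf sets (as sorted integer vectors) under each internal node of an
# hclust merge matrix.
node_clades <- function(hc) {
  n <- length(hc$order)
  clades <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    members <- integer(0)
    for (child in hc$merge[i, ]) {
      members <- c(members,
                   if (child < 0) -child else clades[[child]])
    }
    clades[[i]] <- sort(members)
  }
  clades
}

clade_key <- function(members) paste(members, collapse = ",")

# Leaf-weight signature of every internal node (sum of leaf weights under
# the node), rounded so that identical clades built in different merge
# orders hash identically despite floating-point addition order.
node_sigs <- function(hc, w) {
  m <- hc$merge
  n1 <- nrow(m)
  sig <- numeric(n1)
  for (i in seq_len(n1)) {
    a <- m[i, 1]
    b <- m[i, 2]
    sig[i] <- (if (a < 0) w[-a] else sig[a]) +
              (if (b < 0) w[-b] else sig[b])
  }
  round(sig * 1e9)
}

#' Multiscale bootstrap support for a profile dendrogram
#'
#' Estimates per-node bootstrap probabilities (BP) at several resample
#' scales by resampling the *feature columns* of the profile matrix with
#' replacement, re-clustering, and counting how often each original clade
#' reappears. Approximately unbiased (AU) p-values are then obtained by the
#' signed-distance extrapolation: with `z_r = qnorm(1 - BP_r)` and scale
#' `r' = round(r * p) / p`, a weighted least-squares fit of
#' `z_r = v * sqrt(r') + c / sqrt(r')` (weights from the binomial variance
#' of BP) gives `AU = 1 - pnorm(v - c)`. Scales at which a node's BP is
#' exactly 0 or 1 carry no information about the curvature and are excluded
#' from the fit; nodes with fewer than 3 informative scales fall back to
#' their BP at the scale closest to 1, clipped to `[1/(2B), 1 - 1/(2B)]`,
#' and are flagged.
#'
#' @param profiles a [clump_profiles] matrix.
#' @param tree the [ward_tree] of `profiles` (recomputed if `NULL`).
#' @param scales resample-size multipliers (default `seq(0.5, 1.4, 0.1)`).
#' @param B bootstrap replicates per scale.
#' @param seed integer seed.
#' @param variant Ward variant passed to [ward_tree].
#' @return An object of class `cluster_tree`: list with `hclust`, `clades`,
#'   `bp` (nodes x scales matrix of raw BP), `au`, `au_method`
#'   (`"wls"`/`"bp"` per node), `scales`, `scales_eff`, `B`.
#' @export
multiscale_bootstrap <- function(profiles, tree = NULL,
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 B = 1000L, seed = 1L,
                                 variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  p <- ncol(profiles)
  if (p < 2L) stop("profiles needs at least 2 feature columns")
  if (is.null(tree)) tree <- ward_tree(profiles, variant)
  hc <- as_hclust(tree)
  n <- length(hc$order)
  clades <- node_clades(hc)
  sizes_eff <- pmax(2L, round(scales * p))
  bp <- matrix(0, nrow = n - 1L, ncol = length(scales),
               dimnames = list(NULL, paste0("r", scales)))
  seeds <- derive_seeds(seed, length(scales) + 1L, stream = 3L)
  # clade identity via random-weight signatures: the signature of a clade is
  # the sum of its leaves' weights, computed in one pass over the merge
  # matrix (numeric hashing; collisions vanishingly unlikely at this scale)
  w <- with_seed(seeds[length(scales) + 1L], stats::runif(n))
  sigs <- node_sigs(hc, w)
  pm <- t(profiles)
  for (s_i in seq_along(scales)) {
    hits <- with_seed(seeds[s_i], {
      acc <- integer(n - 1L)
      for (b in seq_len(B)) {
        cols <- sample.int(p, sizes_eff[s_i], replace = TRUE)
        cc <- suppressWarnings(stats::cor(pm[cols, , drop = FALSE]))
        cc[!is.finite(cc)] <- 0  # degenerate rows: treat as uncorrelated
        hb <- stats::hclust(stats::as.dist(1 - cc), method = variant)
        acc <- acc + !is.na(match(sigs, node_sigs(hb, w)))
      }
      acc
    })
    bp[, s_i] <- hits / B
  }
  r_eff <- sizes_eff / p
  clip <- function(x) pmin(pmax(x, 1 / (2 * B)), 1 - 1 / (2 * B))
  au <- numeric(n - 1L)
  method <- character(n - 1L)
  near1 <- which.min(abs(r_eff - 1))
  for (i in seq_len(n - 1L)) {
    usable <- which(bp[i, ] > 0 & bp[i, ] < 1)
    if (length(usable) >= 3L) {
      bpc <- bp[i, usable]
      z <- stats::qnorm(1 - bpc)
      rr <- r_eff[usable]
      w <- B * stats::dnorm(z)^2 / (bpc * (1 - bpc))
      X <- cbind(sqrt(rr), 1 / sqrt(rr))
      fit <- stats::lm.wfit(X, z, w)
      vc <- fit$coefficients
      if (anyNA(vc)) {
        au[i] <- clip(bp[i, near1])
        method[i] <- "bp"
      } else {
        au[i] <- 1 - stats::pnorm(vc[1] - vc[2])
        method[i] <- "wls"
      }
    } else {
      au[i] <- clip(bp[i, near1])
      method[i] <- "bp"
    }
  }
  structure(list(hclust = hc, clades = clades, bp = bp, au = au,
                 au_method = method, scales = scales, scales_eff = r_eff,
                 B = as.integer(B)),
            class = "cluster_tree")
}

#' @exportS3Method base::print
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d leaves, %d nodes; AU in [%.3f, %.3f] (%d of %d by WLS)\n",
              length(x$hclust$order), length(x$au), min(x$au), max(x$au),
              sum(x$au_method == "wls"), length(x$au)))
  invisible(x)
}

#' Extract confident clusters from AU values
#'
#' Walks the dendrogram from below the root and reports every *outermost*
#' internal node whose AU support reaches `1 - alpha` as a cluster; members
#' not covered by any such node stay unassigned (`NA`). The root clade is
#' not a candidate: the full leaf set is present in every bootstrap tree by
#' construction, so its support carries no information (the same convention
#' the standard AU-clustering tools use when extracting clusters).
#'
#' @param tree a [multiscale_bootstrap] result.
#' @param alpha significance level (default 0.05: clusters with AU >= 0.95).
#' @return Named integer vector over the tree's leaves (clumps); `NA` marks
#'   unassigned members. Attribute `clusters` holds the member index sets.
#' @export
pick_confident <- function(tree, alpha = 0.05) {
  stopifnot(inherits(tree, "cluster_tree"))
  hc <- tree$hclust
  n <- length(hc$order)
  thr <- 1 - alpha
  found <- list()
  walk <- function(node) {
    if (tree$au[node] >= thr) {
      found[[length(found) + 1L]] <<- tree$clades[[node]]
      return(invisible(NULL))
    }
    for (child in hc$merge[node, ]) if (child > 0) walk(child)
    invisible(NULL)
  }
  if (n > 2L) {
    for (child in hc$merge[n - 1L, ]) if (child > 0) walk(child)
  }
  labels <- rep(NA_integer_, n)
  for (c_i in seq_along(found)) labels[found[[c_i]]] <- c_i
  names(labels) <- if (!is.null(hc$labels)) hc$labels else as.character(seq_len(n))
  attr(labels, "clusters") <- found
  labels
}

#' Automatic choice of the number of clusters
#'
#' Compares the confident (AU-supported) partial partition with complete
#' `k`-cluster cuts of the same tree and returns the smallest `k` whose cut
#' is maximally similar (ARI) to the confident partition. Unassigned members
#' of the confident partition are treated as singletons.
#'
#' @param tree a [multiscale_bootstrap] result.
#' @param confident result of [pick_confident] (recomputed with `alpha` if
#'   `NULL`).
#' @param k_range candidate cluster numbers (default `2..min(30, n - 1)`).
#' @param alpha used only when `confident` is `NULL`.
#' @return The chosen `k` (integer), with attribute `ari` (the ARI profile
#'   over `k_range`).
#' @export
choose_k <- function(tree, confident = NULL,
                     k_range = NULL, alpha = 0.05) {
  stopifnot(inherits(tree, "cluster_tree"))
  n <- length(tree$hclust$order)
  if (is.null(confident)) confident <- pick_confident(tree, alpha)
  if (all(is.na(confident)))
    stop("no confident clusters at this alpha; choose k manually")
  if (is.null(k_range)) k_range <- 2:max(2L, min(30L, n - 1L))
  ref <- as.integer(confident)
  na_idx <- which(is.na(ref))
  ref[na_idx] <- max(ref, 0L, na.rm = TRUE) + seq_along(na_idx)  # singletons
  aris <- vapply(k_range, function(k) {
    adjusted_rand_index(cut_clusters(tree, k), ref)
  }, numeric(1))
  best <- k_range[which.max(aris)]  # which.max takes the first (smallest k)
  attr(best, "ari") <- stats::setNames(aris, k_range)
  best
}
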