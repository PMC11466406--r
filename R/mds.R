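#' Minimum dominating sets and control nodes
#'
#' A dominating set of an undirected graph is a vertex subset `S` such that
#' every vertex is in `S` or adjacent to a member of `S` (closed-neighbourhood
#' domination); the MDS is a smallest such set. The binary program
#' `min sum(x_v)` subject to `x_v + sum(x_u, u in N(v)) >= 1` is solved
#' exactly by branch-and-bound on the covering constraints, independently on
#' every connected component (isolated vertices are always included).
#'
#' @param g an undirected igraph graph with named vertices.
#' @return `min_dominating_set`: a character vector, one optimal set.
#' @seealso [enumerate_optimal_mds] for all alternative optima and the
#'   critical/intermittent classification, [brute_force_mds] for the
#'   exhaustive oracle.
#' @export
min_dominating_set <- function(g) {
  comp <- split_components(g)
  unlist(lapply(comp, function(cc) {
    sol <- dom_branch_bound(cc$nbhd)
    cc$names[sol$best_set]
  }), use.names = FALSE)
}

#' Exhaustive minimum-dominating-set search (test oracle)
#'
#' Enumerates vertex subsets in increasing size and returns the minimum size
#' together with the complete list of optima. Refuses graphs with more than
#' 20 vertices.
#'
#' @param g an undirected igraph graph with named vertices, `|V| <= 20`.
#' @return List with `size` (integer) and `solutions` (list of character
#'   vectors, every optimal set).
#' @export
brute_force_mds <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("graph must be nonempty")
  if (n > 20L) stop("brute force refuses graphs with more than 20 vertices")
  nb <- closed_neighbourhoods(g)
  masks <- vapply(nb, function(v) sum(bitwShiftL(1L, v - 1L)), numeric(1))
  full <- sum(bitwShiftL(1L, seq_len(n) - 1L))
  vnames <- igraph::V(g)$name
  for (s in seq_len(n)) {
    sols <- list()
    cmb <- utils::combn(n, s)
    for (j in seq_len(ncol(cmb))) {
      sel <- cmb[, j]
      if (sum_mask(masks[sel]) == full) sols[[length(sols) + 1L]] <- vnames[sel]
    }
    if (length(sols)) return(list(size = s, solutions = sols))
  }
  stop("unreachable")
}

# OR-combine vertex cover masks (doubles used as 20-bit integers)
sum_mask <- function(ms) {
  acc <- 0
  for (m in ms) acc <- bitwOr(as.integer(acc), as.integer(m))
  acc
}

#' Enumerate alternative optimal MDSs; critical and intermittent nodes
#'
#' Finds the optimal size, then enumerates distinct optimal sets (up to
#' `n_solutions`, the published default of 15 repeated solves) by a
#' branch-and-bound search whose branching partitions the solution space, so
#' no optimum is produced twice and enumeration stops early when fewer optima
#' exist. Vertices present in every enumerated optimum are *critical*;
#' vertices present in at least one but not all are *intermittent* (the two
#' classes are disjoint).
#'
#' @param g an undirected igraph graph with named vertices.
#' @param n_solutions maximum number of optima to enumerate per component.
#' @return An object of class `control_set`: list with `mds_size`,
#'   `solutions` (list of character vectors), `critical`, `intermittent`,
#'   `n_optima` (total count of optima, `NA` if enumeration was truncated),
#'   and `solution_count` (per-gene appearances among the listed solutions).
#' @export
enumerate_optimal_mds <- function(g, n_solutions = 15L) {
  stopifnot(n_solutions >= 1)
  comp <- split_components(g)
  per <- lapply(comp, function(cc) {
    opt <- dom_branch_bound(cc$nbhd)
    en <- dom_enumerate(cc$nbhd, opt$best_size, cap = n_solutions)
    list(size = opt$best_size,
         sets = lapply(en$solutions, function(s) cc$names[s]),
         complete = en$complete)
  })
  mds_size <- sum(vapply(per, `[[`, integer(1), "size"))
  critical <- unlist(lapply(per, function(p) Reduce(intersect, p$sets)),
                     use.names = FALSE)
  all_members <- unique(unlist(lapply(per, function(p) unique(unlist(p$sets)))))
  complete <- all(vapply(per, `[[`, logical(1), "complete"))
  counts <- vapply(per, function(p) length(p$sets), integer(1))
  n_optima <- if (complete) prod(counts) else NA_integer_
  solutions <- cross_product_solutions(lapply(per, `[[`, "sets"), n_solutions)
  sc <- table(unlist(solutions))
  structure(list(mds_size = mds_size, solutions = solutions,
                 critical = sort(critical),
                 intermittent = sort(setdiff(all_members, critical)),
                 n_optima = n_optima,
                 solution_count = sc[order(names(sc))]),
            class = "control_set")
}

#' @exportS3Method base::print
print.control_set <- function(x, ...) {
  cat(sprintf("<control_set> |MDS| = %d; %s optima; %d critical, %d intermittent\n",
              x$mds_size,
              if (is.na(x$n_optima)) paste0(">=", length(x$solutions))
              else x$n_optima,
              length(x$critical), length(x$intermittent)))
  invisible(x)
}

#' Check the domination property
#'
#' @param g an undirected igraph graph with named vertices.
#' @param s character vector of vertex names.
#' @return TRUE iff every vertex of `g` is in `s` or adjacent to a member.
#' @export
is_dominating_set <- function(g, s) {
  nb <- closed_neighbourhoods(g)
  sel <- match(s, igraph::V(g)$name)
  if (anyNA(sel)) stop("unknown vertex in s")
  dominated <- logical(igraph::vcount(g))
  for (v in sel) dominated[nb[[v]]] <- TRUE
  all(dominated)
}

closed_neighbourhoods <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) stop("graph must be nonempty")
  adj <- igraph::as_adj_list(g, mode = "all")
  lapply(seq_along(adj), function(v) sort(unique(c(v, as.integer(adj[[v]])))))
}

split_components <- function(g) {
  nb <- closed_neighbourhoods(g)
  memb <- igraph::components(g)$membership
  vnames <- igraph::V(g)$name
  if (is.null(vnames)) vnames <- as.character(seq_along(memb))
  lapply(split(seq_along(memb), memb), function(vs) {
    remap <- integer(length(memb))
    remap[vs] <- seq_along(vs)
    list(names = vnames[vs],
         nbhd = lapply(nb[vs], function(x) remap[x]))
  })
}

# Branch and bound for the minimum dominating set of one connected component.
# nbhd: list of closed neighbourhoods on local indices 1..n.
dom_branch_bound <- function(nbhd) {
  n <- length(nbhd)
  cover_of <- nbhd                      # vertices covered when u is chosen
  maxcov <- max(lengths(cover_of))
  # greedy upper bound
  dominated <- logical(n)
  greedy <- integer(0)
  while (!all(dominated)) {
    gains <- vapply(cover_of, function(cv) sum(!dominated[cv]), integer(1))
    u <- which.max(gains)
    greedy <- c(greedy, u)
    dominated[cover_of[[u]]] <- TRUE
  }
  env <- new.env(parent = emptyenv())
  env$best_size <- length(greedy)
  env$best_set <- greedy
  recurse <- function(dominated, chosen, banned) {
    undom <- which(!dominated)
    if (!length(undom)) {
      if (length(chosen) < env$best_size) {
        env$best_size <- length(chosen)
        env$best_set <- chosen
      }
      return(invisible(NULL))
    }
    lb <- length(chosen) + ceiling(length(undom) / maxcov)
    if (lb >= env$best_size) return(invisible(NULL))
    # branch on the undominated vertex with the fewest allowed dominators
    cand_list <- lapply(undom, function(v) nbhd[[v]][!banned[nbhd[[v]]]])
    sizes <- lengths(cand_list)
    if (any(sizes == 0L)) return(invisible(NULL))
    v_i <- which.min(sizes)
    cands <- cand_list[[v_i]]
    gains <- vapply(cands, function(u) sum(!dominated[cover_of[[u]]]),
                    integer(1))
    cands <- cands[order(-gains)]
    for (u in cands) {
      d2 <- dominated
      d2[cover_of[[u]]] <- TRUE
      recurse(d2, c(chosen, u), banned)
      banned[u] <- TRUE
    }
    invisible(NULL)
  }
  recurse(logical(n), integer(0), logical(n))
  list(best_size = env$best_size, best_set = sort(env$best_set))
}

# Enumerate all dominating sets of exactly `target` vertices (= all optima
# when target is the optimal size) for one component; the banning scheme
# partitions the search space so solutions are distinct and complete unless
# `cap` is reached.
dom_enumerate <- function(nbhd, target, cap = 15L) {
  n <- length(nbhd)
  cover_of <- nbhd
  maxcov <- max(lengths(cover_of))
  env <- new.env(parent = emptyenv())
  env$solutions <- list()
  env$complete <- TRUE
  recurse <- function(dominated, chosen, banned) {
    if (length(env$solutions) >= cap) {
      env$complete <- FALSE
      return(invisible(NULL))
    }
    undom <- which(!dominated)
    if (!length(undom)) {
      if (length(chosen) == target)
        env$solutions[[length(env$solutions) + 1L]] <- sort(chosen)
      return(invisible(NULL))
    }
    remaining <- target - length(chosen)
    if (remaining <= 0L) return(invisible(NULL))
    if (ceiling(length(undom) / maxcov) > remaining) return(invisible(NULL))
    cand_list <- lapply(undom, function(v) nbhd[[v]][!banned[nbhd[[v]]]])
    sizes <- lengths(cand_list)
    if (any(sizes == 0L)) return(invisible(NULL))
    v_i <- which.min(sizes)
    cands <- sort(cand_list[[v_i]])  # deterministic order
    for (u in cands) {
      d2 <- dominated
      d2[cover_of[[u]]] <- TRUE
      recurse(d2, c(chosen, u), banned)
      banned[u] <- TRUE
      if (!env$complete) break
    }
    invisible(NULL)
  }
  recurse(logical(n), integer(0), logical(n))
  list(solutions = env$solutions, complete = env$complete)
}

# Cartesian product of per-component solution lists, truncated to `cap`
# entries (mixed-radix order).
cross_product_solutions <- function(sets_by_comp, cap) {
  counts <- vapply(sets_by_comp, length, integer(1))
  total <- prod(counts)
  n_out <- min(cap, total)
  out <- vector("list", n_out)
  for (i in seq_len(n_out)) {
    rem <- i - 1L
    pick <- integer(length(counts))
    for (c_i in seq_along(counts)) {
      pick[c_i] <- rem %% counts[c_i] + 1L
      rem <- rem %/% counts[c_i]
    }
    out[[i]] <- sort(unlist(Map(function(ss, p) ss[[p]], sets_by_comp, pick),
                            use.names = FALSE))
  }
  out
}
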