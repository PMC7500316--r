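# Network resilience: relative giant-connected-component curves under
# random failure and targeted attack. Curves over a whole removal order
# are computed by reverse node addition with union-find, which makes
# averaging over many random orders cheap.

# Giant-component size after removing the first k nodes of `order`, for
# k = 0..n, via reverse addition with union-find (path halving).
#' @noRd
gcc_curve_for_order <- function(nbrs, n, ord) {
  parent <- integer(n)
  csize <- integer(n)
  present <- logical(n)
  gcc <- integer(n + 1)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  best <- 0L
  for (idx in n:1) {
    v <- ord[idx]
    parent[v] <- v
    csize[v] <- 1L
    present[v] <- TRUE
    for (u in nbrs[[v]]) {
      if (present[u]) {
        ru <- find(u)
        rv <- find(v)
        if (ru != rv) {
          if (csize[ru] < csize[rv]) { tmp <- ru; ru <- rv; rv <- tmp }
          parent[rv] <- ru
          csize[ru] <- csize[ru] + csize[rv]
        }
      }
    }
    sz <- csize[find(v)]
    if (sz > best) best <- sz
    gcc[idx] <- best
  }
  gcc # gcc[k + 1] = giant component size after removing first k nodes
}

#' @noRd
new_resilience_curve <- function(strategy, rel_gcc, n, n_orders = NA_integer_,
                                 seed = NULL, rank_by = NA_character_,
                                 recompute = NA) {
  structure(
    list(strategy = strategy, n_removed = 0:n, rel_gcc = rel_gcc,
         n_orders = n_orders, seed = seed, rank_by = rank_by,
         recompute = recompute),
    class = "scov_resilience"
  )
}

#' @export
print.scov_resilience <- function(x, ...) {
  cat(sprintf("<scov_resilience> %s over %d nodes\n",
              x$strategy, length(x$n_removed) - 1))
  invisible(x)
}

#' Resilience to random node failure
#'
#' Removes nodes one at a time in uniformly random order, tracking the
#' size of the giant connected component relative to the largest component
#' of the intact network, and averages the curve over `n_orders`
#' independent removal orders (a single random pass is noise-dominated;
#' set `n_orders = 1` for a literal single realization). With
#' `exact = TRUE` the exact expectation over all removal orders is
#' computed by enumerating residual node subsets (feasible up to ~20
#' nodes), using the fact that the first k positions of a uniform random
#' order form a uniform random k-subset.
#'
#' @param A binary symmetric adjacency matrix, at least 2 nodes.
#' @param n_orders number of random removal orders to average (default
#'   100).
#' @param seed integer seed.
#' @param exact compute the exact expected curve by subset enumeration.
#' @return A `scov_resilience` with `rel_gcc[k + 1]` the relative giant
#'   component size after removing k nodes; starts at 1 and ends at 0.
#' @export
random_failure_curve <- function(A, n_orders = 100, seed = NULL,
                                 exact = FALSE) {
  A <- check_adjacency(A)
  n <- nrow(A)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  gcc0 <- largest_component_size(A)
  if (exact) {
    if (n > 20) stop("`exact = TRUE` is limited to 20 nodes", call. = FALSE)
    rel <- numeric(n + 1)
    rel[1] <- 1
    for (k in seq_len(n)) {
      if (k == n) { rel[k + 1] <- 0; next }
      removed_sets <- utils::combn(n, k, simplify = FALSE)
      sizes <- vapply(removed_sets, function(s) {
        keep <- setdiff(seq_len(n), s)
        largest_component_size(A[keep, keep, drop = FALSE])
      }, numeric(1))
      rel[k + 1] <- mean(sizes) / gcc0
    }
    return(new_resilience_curve("random_failure", rel, n,
                                n_orders = NA_integer_, seed = seed))
  }
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  with_seed(seed, {
    acc <- numeric(n + 1)
    for (r in seq_len(n_orders)) {
      ord <- sample.int(n)
      acc <- acc + gcc_curve_for_order(nbrs, n, ord)
    }
    rel <- acc / n_orders / gcc0
    new_resilience_curve("random_failure", rel, n, n_orders = n_orders,
                         seed = seed)
  })
}

#' Resilience to targeted attack
#'
#' Removes nodes in decreasing order of a centrality -- betweenness (as
#' used for the attack curves this package reports) or degree. By default
#' the ranking is computed once on the intact network; with
#' `recompute = TRUE` the centrality is recomputed on the surviving
#' network after every removal. Ties are broken by ascending node index,
#' so the attack is fully deterministic.
#'
#' @param A binary symmetric adjacency matrix, at least 2 nodes.
#' @param rank_by `"betweenness"` (default) or `"degree"`.
#' @param recompute recompute the centrality after each removal.
#' @return A `scov_resilience` (strategy `targeted_betweenness` or
#'   `targeted_degree`).
#' @export
targeted_attack_curve <- function(A, rank_by = c("betweenness", "degree"),
                                  recompute = FALSE) {
  rank_by <- match.arg(rank_by)
  A <- check_adjacency(A)
  n <- nrow(A)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  gcc0 <- largest_component_size(A)
  centrality <- function(M) {
    if (rank_by == "degree") rowSums(M)
    else igraph::betweenness(adjacency_to_graph(M), directed = FALSE,
                             weights = NA)
  }
  if (!recompute) {
    score <- centrality(A)
    ord <- order(-score, seq_len(n))
    nbrs <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
    rel <- gcc_curve_for_order(nbrs, n, ord) / gcc0
  } else {
    alive <- seq_len(n)
    rel <- numeric(n + 1)
    rel[1] <- 1
    M <- A
    for (k in seq_len(n)) {
      score <- centrality(M)
      pick <- which.max(score) # first maximum = lowest surviving index
      alive <- alive[-pick]
      M <- M[-pick, -pick, drop = FALSE]
      rel[k + 1] <- if (length(alive)) largest_component_size(M) / gcc0 else 0
    }
  }
  new_resilience_curve(paste0("targeted_", rank_by), rel, n,
                       rank_by = rank_by, recompute = recompute)
}
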