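# Graph-theoretical measures for binary undirected networks, small-world
# normalization against degree-preserving null ensembles, and normalized
# nodal betweenness. Path-based measures run on a dense all-pairs BFS
# (see utils-graph.R); betweenness uses Brandes' algorithm via igraph so
# multiple equal-length shortest paths are credited fractionally.

#' Mean clustering coefficient
#'
#' Watts-Strogatz clustering per node (realized over possible triangles
#' among its neighbours; nodes with degree < 2 contribute 0), averaged
#' unweighted over all nodes.
#'
#' @param A binary symmetric adjacency matrix with zero diagonal.
#' @return Scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(A) {
  A <- check_adjacency(A)
  deg <- rowSums(A)
  tri <- rowSums((A %*% A) * A) / 2 # closed triangles at each node
  poss <- deg * (deg - 1) / 2
  ci <- ifelse(deg < 2, 0, tri / pmax(poss, 1))
  mean(ci)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all unordered node pairs. Pairs in
#' different components carry no finite distance; they are excluded from
#' the mean and flagged via the `"disconnected"` attribute, so that
#' permuted or sparse networks that fall apart yield finite values rather
#' than infinities.
#'
#' @param A binary symmetric adjacency matrix with at least one edge.
#' @return Scalar path length (>= 1) with attribute `disconnected`.
#' @export
characteristic_path_length <- function(A) {
  A <- check_adjacency(A)
  if (sum(A) == 0) stop("network has no edges", call. = FALSE)
  D <- bfs_distances(A)
  d <- D[upper.tri(D)]
  fin <- is.finite(d)
  structure(mean(d[fin]), disconnected = !all(fin))
}

#' Global efficiency
#'
#' Mean over all unordered node pairs of the inverse shortest-path
#' distance, with disconnected pairs contributing 0.
#'
#' @param A binary symmetric adjacency matrix.
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(A) {
  A <- check_adjacency(A)
  n <- nrow(A)
  if (n < 2) return(0)
  D <- bfs_distances(A)
  inv <- 1 / D[upper.tri(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by
#' each node's neighbours (the node itself excluded); nodes with degree
#' < 2 contribute 0. Captures fault tolerance of the immediate
#' neighbourhood to removal of the node.
#'
#' @param A binary symmetric adjacency matrix.
#' @return Scalar in \[0, 1\].
#' @export
local_efficiency <- function(A) {
  A <- check_adjacency(A)
  n <- nrow(A)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) >= 2) {
      D <- bfs_distances(A[nb, nb, drop = FALSE])
      inv <- 1 / D[upper.tri(D)]
      inv[!is.finite(inv)] <- 0
      e[i] <- mean(inv)
    }
  }
  mean(e)
}

#' Nodal betweenness, raw and normalized
#'
#' Shortest-path betweenness per node, with fractional crediting when a
#' pair is joined by several equal-length shortest paths, normalized by
#' the network-average betweenness so values are comparable across
#' densities and groups. When the average raw betweenness is 0 (e.g. a
#' complete graph) the normalized values are defined as all zeros and
#' flagged.
#'
#' @param A binary symmetric adjacency matrix.
#' @return A list with `raw`, `norm` (mean 1 whenever defined) and the
#'   logical flag `degenerate`.
#' @export
nodal_betweenness <- function(A) {
  A <- check_adjacency(A)
  g <- adjacency_to_graph(A)
  raw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  names(raw) <- colnames(A)
  m <- mean(raw)
  if (m == 0) {
    warning("mean betweenness is zero; normalized betweenness set to 0",
            call. = FALSE)
    norm <- raw * 0
    degenerate <- TRUE
  } else {
    norm <- raw / m
    degenerate <- FALSE
  }
  list(raw = raw, norm = norm, degenerate = degenerate)
}

#' Degree-preserving null ensemble
#'
#' Randomizes the network by Maslov-Sneppen double-edge swaps: repeatedly
#' pick two edges (a,b), (c,d) and rewire to (a,d), (c,b) unless that would
#' create a self-loop or multi-edge. Each null starts from the source
#' network and attempts `swaps_per_edge * E` swaps, so the degree sequence
#' is preserved exactly while triangles and path structure are destroyed.
#' Connectivity is not enforced. A warning is raised when fewer than 10%
#' of attempted swaps succeed (near-regular or saturated graphs barely
#' randomize).
#'
#' @param A binary symmetric adjacency matrix with >= 2 edges.
#' @param n_nulls ensemble size (default 20).
#' @param seed integer seed for reproducibility.
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @return A `scov_null_ensemble`: list with `networks` (list of
#'   adjacencies), `cp_rand` and `lp_rand` (arithmetic means over the
#'   ensemble), `acceptance` and `seed`.
#' @export
make_null_ensemble <- function(A, n_nulls = 20, seed = NULL,
                               swaps_per_edge = 10) {
  A <- check_adjacency(A)
  if (sum(A) / 2 < 2) stop("need at least 2 edges to rewire", call. = FALSE)
  with_seed(seed, {
    nets <- vector("list", n_nulls)
    acc <- numeric(n_nulls)
    for (j in seq_len(n_nulls)) {
      sw <- double_edge_swap(A, swaps_per_edge)
      nets[[j]] <- sw$adjacency
      acc[j] <- sw$acceptance
    }
    if (mean(acc) < 0.10) {
      warning(sprintf(
        "null-model swap acceptance ratio %.2f < 0.10; the graph barely randomizes",
        mean(acc)), call. = FALSE)
    }
    cp <- vapply(nets, clustering_coefficient, numeric(1))
    lp <- vapply(nets, function(x) as.numeric(characteristic_path_length(x)),
                 numeric(1))
    structure(
      list(networks = nets, cp_rand = mean(cp), lp_rand = mean(lp),
           acceptance = mean(acc), seed = seed),
      class = "scov_null_ensemble"
    )
  })
}

#' @noRd
double_edge_swap <- function(A, swaps_per_edge = 10) {
  ut <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  E <- nrow(ut)
  ei <- ut[, 1]
  ej <- ut[, 2]
  attempts <- ceiling(swaps_per_edge * E)
  # pre-drawn randomness keeps the rejection loop tight
  pick1 <- sample.int(E, attempts, replace = TRUE)
  pick2 <- sample.int(E, attempts, replace = TRUE)
  flip <- stats::runif(attempts) < 0.5
  accepted <- 0L
  for (t in seq_len(attempts)) {
    i1 <- pick1[t]
    i2 <- pick2[t]
    if (i1 == i2) next
    a <- ei[i1]; b <- ej[i1]
    if (flip[t]) { c <- ej[i2]; d <- ei[i2] } else { c <- ei[i2]; d <- ej[i2] }
    # proposal: (a,b),(c,d) -> (a,d),(c,b)
    if (a == d || c == b || a == c || b == d) next
    if (A[a, d] == 1 || A[c, b] == 1) next
    A[a, b] <- 0; A[b, a] <- 0
    A[c, d] <- 0; A[d, c] <- 0
    A[a, d] <- 1; A[d, a] <- 1
    A[c, b] <- 1; A[b, c] <- 1
    ei[i1] <- min(a, d); ej[i1] <- max(a, d)
    ei[i2] <- min(c, b); ej[i2] <- max(c, b)
    accepted <- accepted + 1L
  }
  list(adjacency = A, acceptance = accepted / attempts)
}

#' Global metrics without null normalization
#'
#' Computes the four density-wise global measures in one pass: clustering
#' coefficient, characteristic path length, global and local efficiency.
#'
#' @param A binary symmetric adjacency matrix.
#' @return Named list `cp`, `lp`, `e_glob`, `e_loc`, plus the
#'   `disconnected` flag of the path length.
#' @export
global_metrics <- function(A) {
  A <- check_adjacency(A)
  lp <- characteristic_path_length(A)
  list(cp = clustering_coefficient(A),
       lp = as.numeric(lp),
       e_glob = global_efficiency(A),
       e_loc = local_efficiency(A),
       disconnected = isTRUE(attr(lp, "disconnected")))
}

#' Small-world parameters against a null ensemble
#'
#' Normalizes clustering and path length by their means over a
#' degree-preserving null ensemble: `gamma = Cp/Cp_rand`,
#' `lambda = Lp/Lp_rand`, and the small-world index
#' `sigma = gamma/lambda`. A network is called small-world when
#' `gamma > 1` with `lambda` near 1, equivalently `sigma > 1`.
#'
#' @param A binary symmetric adjacency matrix.
#' @param ensemble a [make_null_ensemble()] built from the same network.
#' @return A `scov_global` list: `cp`, `lp`, `e_glob`, `e_loc`, `gamma`,
#'   `lambda`, `sigma`, `cp_rand`, `lp_rand`, `disconnected`.
#' @export
small_world <- function(A, ensemble) {
  stopifnot(inherits(ensemble, "scov_null_ensemble"))
  gm <- global_metrics(A)
  if (!is.finite(ensemble$cp_rand) || ensemble$cp_rand == 0) {
    stop("null ensemble has zero mean clustering; gamma undefined",
         call. = FALSE)
  }
  if (!is.finite(ensemble$lp_rand) || ensemble$lp_rand <= 0) {
    stop("null ensemble has undefined mean path length; lambda undefined",
         call. = FALSE)
  }
  gamma <- gm$cp / ensemble$cp_rand
  lambda <- gm$lp / ensemble$lp_rand
  structure(
    c(gm[c("cp", "lp", "e_glob", "e_loc")],
      list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
           cp_rand = ensemble$cp_rand, lp_rand = ensemble$lp_rand,
           disconnected = gm$disconnected)),
    class = "scov_global"
  )
}

#' @export
print.scov_global <- function(x, ...) {
  cat(sprintf(
    "<scov_global> Cp %.3f  Lp %.3f  Eglob %.3f  Eloc %.3f  gamma %.2f  lambda %.2f  sigma %.2f\n",
    x$cp, x$lp, x$e_glob, x$e_loc, x$gamma, x$lambda, x$sigma))
  invisible(x)
}
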