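# Internal graph utilities shared by the metric, resilience and network
# construction code. All public entry points operate on plain binary
# symmetric adjacency matrices with a zero diagonal; these helpers validate
# and traverse them without building heavier graph objects in hot loops.

#' @noRd
check_adjacency <- function(A, arg = "adjacency") {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop(sprintf("`%s` must be a square matrix", arg), call. = FALSE)
  }
  if (is.logical(A)) {
    A <- A + 0
  }
  if (any(is.na(A)) || !all(A %in% c(0, 1))) {
    stop(sprintf("`%s` must be binary (0/1) with no missing values", arg),
         call. = FALSE)
  }
  if (any(diag(A) != 0)) {
    stop(sprintf("`%s` must have a zero diagonal (no self-loops)", arg),
         call. = FALSE)
  }
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE))) {
    stop(sprintf("`%s` must be symmetric (undirected network)", arg),
         call. = FALSE)
  }
  A
}

# All-pairs shortest-path lengths of a binary undirected graph by repeated
# boolean matrix products (level-synchronous BFS from all sources at once).
# Disconnected pairs stay Inf. Fast for the dense 90-node networks this
# package works with; exact for any binary graph.
#' @noRd
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  if (n == 0L) return(D)
  diag(D) <- 0
  if (n == 1L) return(D)
  D[A > 0] <- 1
  B <- A
  diag(B) <- 1
  P <- B > 0            # reachable within d steps (including staying put)
  d <- 1
  repeat {
    Pn <- ((P + 0) %*% B) > 0
    new <- Pn & !P
    if (!any(new)) break
    d <- d + 1
    D[new] <- d
    P <- Pn
  }
  D
}

# Size of the largest connected component (label propagation BFS).
#' @noRd
largest_component_size <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(0L)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  seen <- logical(n)
  best <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      size <- size + 1L
      nb <- nbrs[[v]]
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (size > best) best <- size
  }
  best
}

#' @noRd
adjacency_connected <- function(A) {
  n <- nrow(A)
  if (n <= 1L) return(TRUE)
  largest_component_size(A) == n
}

#' @noRd
adjacency_to_graph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

# Deterministic per-iteration seed derivation; keeps values inside the
# 32-bit integer range R requires.
#' @noRd
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 1009 + as.numeric(i) * 7919) %%
               2147483647)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. With seed = NULL the expression runs on the ambient stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
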