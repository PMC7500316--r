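# Brute-force reference implementations and small graph constructors used
# as independent oracles. These are deliberately naive (explicit loops,
# exhaustive enumeration) and share no code with the package internals.

# All-pairs shortest paths by Floyd-Warshall.
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Mean clustering by explicit neighbour-pair counting.
bf_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (A[nb[a], nb[b]] > 0) links <- links + 1
      }
    }
    ci[v] <- links / (k * (k - 1) / 2)
  }
  mean(ci)
}

bf_path_length <- function(A) {
  D <- bf_distances(A)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

bf_global_eff <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- bf_distances(A)
  inv <- 1 / D[upper.tri(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

bf_local_eff <- function(A) {
  n <- nrow(A)
  e <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (length(nb) >= 2) e[v] <- bf_global_eff(A[nb, nb, drop = FALSE])
  }
  mean(e)
}

# Betweenness by exhaustive enumeration of all shortest paths per pair,
# with fractional crediting of interior nodes.
bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  btw <- numeric(n)
  all_paths <- function(s, t) {
    # every shortest s-t path, walking down the distance gradient to t
    if (!is.finite(D[s, t])) return(list())
    extend <- function(path) {
      v <- path[length(path)]
      if (v == t) return(list(path))
      nxt <- which(A[v, ] > 0 & D[, t] == D[v, t] - 1)
      out <- list()
      for (u in nxt) out <- c(out, extend(c(path, u)))
      out
    }
    extend(s)
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      np <- length(paths)
      if (np == 0) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        btw[interior] <- btw[interior] + 1 / np
      }
    }
  }
  btw
}

# Named graph constructors --------------------------------------------

complete_adj <- function(n) {
  A <- matrix(1, n, n)
  diag(A) <- 0
  A
}

star_adj <- function(n) {
  A <- matrix(0, n, n)
  A[1, 2:n] <- 1
  A[2:n, 1] <- 1
  A
}

path_adj <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    A[i, i + 1] <- 1
    A[i + 1, i] <- 1
  }
  A
}

# Two cliques of size `m` joined by a single bridge edge.
bridge_graph_adj <- function(m = 5) {
  n <- 2 * m
  A <- matrix(0, n, n)
  A[1:m, 1:m] <- 1
  A[(m + 1):n, (m + 1):n] <- 1
  diag(A) <- 0
  A[m, m + 1] <- 1
  A[m + 1, m] <- 1
  A
}

# Barbell: two cliques of size m joined through a path of `len` nodes.
barbell_adj <- function(m = 4, len = 1) {
  n <- 2 * m + len
  A <- matrix(0, n, n)
  A[1:m, 1:m] <- 1
  A[(m + len + 1):n, (m + len + 1):n] <- 1
  diag(A) <- 0
  chain <- m:(m + len + 1)
  for (i in seq_len(length(chain) - 1)) {
    A[chain[i], chain[i + 1]] <- 1
    A[chain[i + 1], chain[i]] <- 1
  }
  A
}

random_adj <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

ws_adj <- function(n, k, p, seed) {
  set.seed(seed)
  g <- igraph::sample_smallworld(1, n, k / 2, p, loops = FALSE,
                                 multiple = FALSE)
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# A small ready-made two-group scenario reused across inference tests.
small_null_pair <- function(seed = 7, n_regions = 16, n = 20) {
  spec <- ground_truth_spec(
    n_regions = n_regions,
    topology = topology_watts_strogatz(4, 0.1),
    base_correlation = 0.5, noise_sd = 0.4, seed = seed)
  generate_paired_cohorts(spec, n_a = n, n_b = n)
}
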