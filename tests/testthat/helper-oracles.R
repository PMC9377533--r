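# Brute-force oracles for the graph metrics, deliberately independent of the
# implementations in R/: Floyd-Warshall for distances, bounded DFS path
# enumeration for shortest-path counts, and explicit triple/pair loops.

oracle_degree <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) sum(A[i, ]), numeric(1))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    k <- sum(A[i, ])
    if (k < 2) return(0)
    tri <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j < h && A[i, j] == 1 && A[i, h] == 1 && A[j, h] == 1) tri <- tri + 1
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

oracle_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# all shortest simple paths from j to k (list of node vectors), found by DFS
# bounded by the known shortest distance
oracle_shortest_path_list <- function(A, j, k, dist) {
  if (!is.finite(dist)) return(list())
  if (j == k) return(list(j))
  paths <- list()
  walk <- function(path, remaining) {
    tail_node <- path[length(path)]
    if (remaining == 0) {
      if (tail_node == k) paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (v in which(A[tail_node, ] == 1)) {
      if (!(v %in% path)) walk(c(path, v), remaining - 1)
    }
  }
  walk(j, dist)
  paths
}

# sigma counts, through counts, and derived CPL/BC, all from enumeration
oracle_spd <- function(A) {
  n <- nrow(A)
  d <- oracle_distances(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  paths <- vector("list", n * n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j != k && is.finite(d[j, k])) {
      pl <- oracle_shortest_path_list(A, j, k, d[j, k])
      sigma[j, k] <- length(pl)
      paths[[(j - 1) * n + k]] <- pl
    }
  }
  list(d = d, sigma = sigma, paths = paths, n = n)
}

oracle_through_count <- function(spd, i, j, k) {
  pl <- spd$paths[[(j - 1) * spd$n + k]]
  if (is.null(pl)) return(0)
  sum(vapply(pl, function(p) i %in% p[-c(1, length(p))], logical(1)))
}

oracle_cpl <- function(spd, policy = "reachable") {
  n <- spd$n
  vapply(seq_len(n), function(i) {
    dd <- spd$d[i, -i]
    if (policy == "literal") mean(dd)
    else if (all(!is.finite(dd))) NaN
    else mean(dd[is.finite(dd)])
  }, numeric(1))
}

oracle_bc <- function(spd) {
  n <- spd$n
  if (n < 3) return(rep(0, n))
  vapply(seq_len(n), function(i) {
    acc <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j < k && j != i && k != i && spd$sigma[j, k] > 0) {
        acc <- acc + oracle_through_count(spd, i, j, k) / spd$sigma[j, k]
      }
    }
    2 * acc / ((n - 1) * (n - 2))
  }, numeric(1))
}

# Erdos-Renyi-style random binary adjacency with given edge probability
random_adjacency <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- as.numeric(stats::runif(length(ut)) < p)
  A + t(A)
}

# random symmetric "correlation-like" matrix with distinct off-diagonal values
random_symmetric <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(stats::rnorm(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  M
}
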