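#' Node-level metrics on binary undirected graphs
#'
#' Degree, clustering coefficient, characteristic path length and betweenness
#' centrality for binary, undirected, zero-diagonal adjacency matrices — the
#' four metrics used to characterise longitudinal functional-network
#' reorganisation.  All functions operate on a plain 0/1 matrix (see
#' [as_adjacency()]) and return a [metric_vector()].
#'
#' @name graph-metrics
NULL

#' Validate and coerce a binary adjacency matrix
#'
#' @param A square numeric matrix with entries in \{0,1\}, symmetric, zero
#'   diagonal.  Dimnames, if present, are kept as node ids.
#' @return the validated matrix, with class attribute untouched.
#' @export
as_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  if (anyNA(A) || !all(A %in% c(0, 1))) {
    stop("adjacency entries must be 0 or 1 with no missing values", call. = FALSE)
  }
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (any(diag(A) != 0)) {
    stop("adjacency diagonal must be zero (no self-loops)", call. = FALSE)
  }
  storage.mode(A) <- "double"
  A
}

#' Construct a metric vector
#'
#' Container tying a per-node metric to its name and provenance; used by all
#' metric functions so downstream longitudinal code can check compatibility.
#'
#' @param metric one of `"D"`, `"CC"`, `"CPL"`, `"BC"`.
#' @param values numeric per-node values.
#' @param provenance optional identifier of the source adjacency.
#' @export
metric_vector <- function(metric = c("D", "CC", "CPL", "BC"), values,
                          provenance = NULL) {
  metric <- match.arg(metric)
  structure(list(metric = metric, values = as.numeric(values),
                 n = length(values), provenance = provenance),
            class = "metric_vector")
}

#' @export
print.metric_vector <- function(x, ...) {
  cat(sprintf("<metric_vector> %s over %d nodes (mean %.4g)\n",
              x$metric, x$n, mean(x$values[is.finite(x$values)])))
  invisible(x)
}

#' Node degree
#'
#' Number of edges incident to each node: row sums of the adjacency matrix.
#'
#' @param adj binary adjacency matrix.
#' @return a `"D"` [metric_vector()] of integer-valued degrees.
#' @export
degree <- function(adj) {
  A <- as_adjacency(adj)
  metric_vector("D", rowSums(A))
}

#' Clustering coefficient
#'
#' Fraction of a node's neighbour pairs that are themselves connected:
#' `CC_i = 2 T_i / (k_i (k_i - 1))` where `T_i` is the number of triangles
#' through node `i` (read off `diag(A^3)/2`) and `k_i` its degree.  Nodes with
#' degree < 2 have no neighbour pair and get `CC = 0` by convention.
#'
#' @inheritParams degree
#' @return a `"CC"` [metric_vector()] with values in \[0, 1\].
#' @export
clustering <- function(adj) {
  A <- as_adjacency(adj)
  k <- rowSums(A)
  tri2 <- diag(A %*% A %*% A)      # = 2 * triangles through i
  cc <- ifelse(k < 2, 0, tri2 / (k * (k - 1)))
  metric_vector("CC", cc)
}

#' All-pairs shortest-path lengths and path counts
#'
#' Level-synchronous breadth-first search run simultaneously from every source
#' using dense matrix products: at hop `L`, the number of shortest `s -> v`
#' walks is the sum over predecessors `u` at hop `L-1` of `sigma_su * a_uv`,
#' which is one row of `frontier %*% A`.  Unreachable pairs keep `Inf` length
#' and zero path count.
#'
#' @inheritParams degree
#' @return an object of class `shortest_path_data` with components
#'   `lengths` (N x N, hops, `Inf` if unreachable, 0 on the diagonal) and
#'   `counts` (N x N, number of distinct shortest paths; `counts[i,i] = 1`).
#' @seealso [path_through_counts()] for per-node pass-through counts.
#' @export
shortest_paths <- function(adj) {
  A <- as_adjacency(adj)
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  sigma <- diag(n)
  frontier <- diag(n)
  level <- 0L
  while (any(frontier > 0)) {
    level <- level + 1L
    nxt <- frontier %*% A
    new <- (nxt > 0) & !is.finite(d)
    if (!any(new)) break
    d[new] <- level
    sigma[new] <- nxt[new]
    frontier <- matrix(0, n, n)
    frontier[new] <- sigma[new]
  }
  structure(list(lengths = d, counts = sigma, n = n),
            class = "shortest_path_data")
}

#' Shortest paths through a given node
#'
#' Number of shortest `j -> k` paths passing through interior node `i`,
#' obtained from the standard decomposition
#' `sigma_jk(i) = sigma_ji * sigma_ik` when `d_ji + d_ik = d_jk` (else 0).
#'
#' @param spd result of [shortest_paths()].
#' @param i node index.
#' @return N x N matrix of through-counts; rows/columns involving `i` are 0.
#' @export
path_through_counts <- function(spd, i) {
  stopifnot(inherits(spd, "shortest_path_data"))
  d <- spd$lengths; s <- spd$counts; n <- spd$n
  stopifnot(i >= 1, i <= n)
  dsum <- outer(d[i, ], d[i, ], "+")
  on_path <- is.finite(dsum) & dsum == d
  through <- outer(s[i, ], s[i, ]) * on_path
  through[i, ] <- 0
  through[, i] <- 0
  diag(through) <- 0
  through
}

#' Characteristic path length per node
#'
#' Average shortest-path hop distance from each node to the other nodes.
#' Under the `"literal"` policy unreachable pairs contribute `Inf`, so any
#' disconnection makes the node's value infinite.  Under the default
#' `"reachable"` policy the average runs over reachable targets only and the
#' number of unreachable targets is reported; isolated nodes are `NaN` and
#' flagged.
#'
#' @param spd result of [shortest_paths()].
#' @param policy `"reachable"` (default) or `"literal"`.
#' @return a `"CPL"` [metric_vector()]; attribute `unreachable` holds the
#'   per-node count of unreachable targets.
#' @export
char_path_length <- function(spd, policy = c("reachable", "literal")) {
  stopifnot(inherits(spd, "shortest_path_data"))
  policy <- match.arg(policy)
  d <- spd$lengths; n <- spd$n
  if (n < 2) stop("characteristic path length needs at least 2 nodes", call. = FALSE)
  off <- d
  diag(off) <- NA
  unreach <- rowSums(!is.na(off) & !is.finite(off))
  if (policy == "literal") {
    vals <- rowMeans(off, na.rm = TRUE)      # Inf propagates
  } else {
    offr <- off
    offr[!is.finite(offr)] <- NA
    vals <- rowMeans(offr, na.rm = TRUE)     # NaN for isolated nodes
  }
  mv <- metric_vector("CPL", vals)
  attr(mv, "unreachable") <- unreach
  mv
}

#' Betweenness centrality
#'
#' Normalised fraction of all-pairs shortest paths passing through each node:
#' `BC_i = 2/((N-1)(N-2)) * sum over unordered pairs {j,k} (j,k != i) of
#' sigma_jk(i)/sigma_jk`, with pairs having no connecting path contributing 0.
#' Values lie in \[0, 1\]; a star centre scores 1.  The pair dependencies are
#' evaluated with the decomposition used by [path_through_counts()], fully
#' vectorised per node.
#'
#' @param spd result of [shortest_paths()].
#' @return a `"BC"` [metric_vector()].
#' @export
betweenness <- function(spd) {
  stopifnot(inherits(spd, "shortest_path_data"))
  d <- spd$lengths; s <- spd$counts; n <- spd$n
  if (n < 3) {
    warning("betweenness undefined for fewer than 3 nodes; returning zeros")
    return(metric_vector("BC", rep(0, n)))
  }
  bc <- numeric(n)
  valid_pair <- is.finite(d) & s > 0       # reachable j-k pairs
  diag(valid_pair) <- FALSE
  for (i in seq_len(n)) {
    dsum <- outer(d[i, ], d[i, ], "+")
    on_path <- valid_pair & is.finite(dsum) & dsum == d
    on_path[i, ] <- FALSE
    on_path[, i] <- FALSE
    if (!any(on_path)) next
    contrib <- (outer(s[i, ], s[i, ]) / s)[on_path]
    bc[i] <- sum(contrib) / 2              # ordered pairs counted twice
  }
  metric_vector("BC", bc * 2 / ((n - 1) * (n - 2)))
}

#' Compute all four node metrics from one adjacency matrix
#'
#' Convenience wrapper sharing a single shortest-path pass between the
#' characteristic path length and betweenness centrality.
#'
#' @inheritParams degree
#' @param cpl_policy passed to [char_path_length()].
#' @param provenance optional source identifier stamped on each metric vector.
#' @return named list with elements `D`, `CC`, `CPL`, `BC`.
#' @export
all_metrics <- function(adj, cpl_policy = "reachable", provenance = NULL) {
  A <- as_adjacency(adj)
  spd <- shortest_paths(A)
  out <- list(D = degree(A), CC = clustering(A),
              CPL = char_path_length(spd, cpl_policy),
              BC = betweenness(spd))
  for (m in names(out)) out[[m]]$provenance <- provenance
  out
}

#' Tidy export of metric vectors
#'
#' @param metrics list of [metric_vector()]s (e.g. from [all_metrics()]).
#' @param subject_id,session identifiers recycled across rows.
#' @return data.frame with columns subject_id, session, node_id, metric, value.
#' @export
metrics_to_df <- function(metrics, subject_id = NA_character_, session = NA_integer_) {
  do.call(rbind, lapply(metrics, function(m) {
    data.frame(subject_id = subject_id, session = session,
               node_id = seq_len(m$n), metric = m$metric, value = m$values,
               stringsAsFactors = FALSE)
  }))
}
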