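#' From node time series to a binary functional-connectivity graph
#'
#' Scrubbing-based subject exclusion, per-node AR pre-whitening, Pearson
#' correlation, proportional thresholding at a fixed edge density, and group
#' averaging of connectivity matrices.
#'
#' @name connectivity
NULL

#' Scrubbing exclusion rule
#'
#' A subject is excluded when strictly more than `limit` volumes were
#' discarded for head motion; a count equal to the limit is still included.
#'
#' @param censored_volume_count non-negative integer count(s) of discarded
#'   volumes.
#' @param limit exclusion threshold (default 30).
#' @return character vector, `"include"` or `"exclude"` per element.
#' @export
scrub_check <- function(censored_volume_count, limit = 30) {
  if (anyNA(censored_volume_count) || any(censored_volume_count < 0)) {
    stop("censored volume counts must be non-negative", call. = FALSE)
  }
  ifelse(censored_volume_count > limit, "exclude", "include")
}

#' Pre-whiten node time series
#'
#' Fits, per column, an autoregressive model of order selected by AIC in
#' `0..max_order` (Yule-Walker) and replaces the column with the model
#' residuals.  Length is preserved by a documented padding convention: the
#' first `p` samples of a column, for which no residual is defined, are kept
#' as the mean-centred original values.  The output is therefore mean-centred
#' throughout, which is immaterial for the Pearson step that follows.
#'
#' @param ts T x N numeric matrix (time points x nodes).
#' @param max_order maximum AR order considered (default 10).
#' @return matrix of the same dimension; attribute `ar_orders` records the
#'   selected order per column.
#' @export
prewhiten <- function(ts, max_order = 10) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 10) stop("need at least 10 time points", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop(sprintf("constant time series at node(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- matrix(0, nrow(ts), ncol(ts), dimnames = dimnames(ts))
  orders <- integer(ncol(ts))
  for (j in seq_len(ncol(ts))) {
    x <- ts[, j]
    fit <- stats::ar(x, aic = TRUE, order.max = max_order,
                     method = "yule-walker")
    p <- fit$order
    orders[j] <- p
    res <- x - mean(x)
    if (p > 0) res[(p + 1):length(x)] <- fit$resid[(p + 1):length(x)]
    out[, j] <- res
  }
  attr(out, "ar_orders") <- orders
  out
}

#' Pearson connectivity matrix
#'
#' Sample Pearson correlation between every pair of node time series, with
#' exact symmetry enforced and unit diagonal (the diagonal is excluded from
#' all downstream thresholding and metrics).
#'
#' @param ts T x N numeric matrix, T >= 3, no zero-variance column.
#' @return N x N symmetric correlation matrix.
#' @export
pearson_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 time points", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance time series at node(s): %s",
                 paste(which(sds == 0), collapse = ", ")), call. = FALSE)
  }
  C <- stats::cor(ts)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C
}

#' Proportional thresholding of a connectivity matrix
#'
#' Keeps the strongest fraction `density` of the `N(N-1)/2` possible edges
#' and binarises: the retained edge count is `E = round(density * N(N-1)/2)`
#' (half away from zero).  "Strongest" ranks by signed correlation by default
#' (most positive first); `mode = "absolute"` ranks by magnitude.  Ties at the
#' cutoff are broken by lexicographic `(i, j)` order so the result is
#' platform-reproducible.
#'
#' @param conn N x N symmetric numeric matrix.
#' @param density target edge density in (0, 1].
#' @param mode `"signed"` (default) or `"absolute"` ranking.
#' @return binary adjacency matrix with attributes `n_edges`,
#'   `achieved_density` and `n_ties_at_cutoff`.
#' @export
proportional_threshold <- function(conn, density = 0.20,
                                   mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (!is.numeric(density) || length(density) != 1 ||
      density <= 0 || density > 1) {
    stop("density must be a single value in (0, 1]", call. = FALSE)
  }
  if (!is.matrix(conn) || nrow(conn) != ncol(conn)) {
    stop("connectivity must be a square matrix", call. = FALSE)
  }
  n <- nrow(conn)
  ut <- which(upper.tri(conn), arr.ind = TRUE)
  vals <- conn[ut]
  if (mode == "absolute") vals <- abs(vals)
  n_possible <- n * (n - 1) / 2
  n_edges <- floor(density * n_possible + 0.5)  # round half away from zero
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(n_edges)]
  A <- matrix(0, n, n, dimnames = dimnames(conn))
  A[ut[keep, , drop = FALSE]] <- 1
  A <- A + t(A)
  ties <- if (n_edges >= 1 && n_edges < n_possible) {
    cutoff <- vals[ord[n_edges]]
    sum(vals == cutoff) - sum(vals[keep] == cutoff)
  } else 0L
  structure(A, n_edges = n_edges,
            achieved_density = n_edges / n_possible,
            n_ties_at_cutoff = as.integer(ties))
}

#' Group-average connectivity matrix
#'
#' Elementwise arithmetic mean of a list of same-shaped correlation matrices.
#' Optional Fisher-z averaging (`tanh(mean(atanh(r)))`) is available but off
#' by default, matching the plain averaging used to build the group maps.
#'
#' @param conns non-empty list of N x N matrices with identical node order.
#' @param fisher average in Fisher-z space (default `FALSE`).
#' @return N x N matrix.
#' @export
group_average <- function(conns, fisher = FALSE) {
  if (!is.list(conns) || length(conns) == 0) {
    stop("need a non-empty list of connectivity matrices", call. = FALSE)
  }
  dims <- vapply(conns, function(m) dim(as.matrix(m)), integer(2))
  if (any(dims != dims[, 1])) stop("matrix shapes differ", call. = FALSE)
  if (fisher) {
    z <- lapply(conns, function(m) atanh(pmin(pmax(m, -1 + 1e-12), 1 - 1e-12)))
    avg <- tanh(Reduce(`+`, z) / length(z))
    diag(avg) <- 1
    avg
  } else {
    Reduce(`+`, lapply(conns, as.matrix)) / length(conns)
  }
}

#' Write an adjacency or connectivity matrix as an upper-triangle edge list
#'
#' @param m square matrix.
#' @param path output file; CSV columns `i,j,weight`, 1-based indices.
#' @export
write_edge_list <- function(m, path) {
  ut <- which(upper.tri(m), arr.ind = TRUE)
  df <- data.frame(i = ut[, 1], j = ut[, 2], weight = m[ut])
  df <- df[df$weight != 0, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
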