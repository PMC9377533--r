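#' Relative longitudinal change of node metrics
#'
#' The change of a metric M between two scanning sessions is expressed
#' relative to its baseline value, `dM = (M2 - M1) / M1`, so a value of 0.5
#' means a 50% increase.  Nodes with a zero baseline have no defined relative
#' change and are flagged, never silently dropped or zero-filled.
#'
#' @name longitudinal
NULL

#' Relative metric change between sessions
#'
#' @param m1,m2 [metric_vector()]s of the same metric, node count and order
#'   (session 1 and session 2).
#' @return object of class `delta_metric`: list with `metric`, `delta`
#'   (numeric, `NA` where undefined), `defined` (logical), `n`.
#' @export
delta_metric <- function(m1, m2) {
  stopifnot(inherits(m1, "metric_vector"), inherits(m2, "metric_vector"))
  if (m1$metric != m2$metric) stop("metric mismatch", call. = FALSE)
  if (m1$n != m2$n) stop("node count mismatch", call. = FALSE)
  defined <- is.finite(m1$values) & is.finite(m2$values) & m1$values != 0
  delta <- rep(NA_real_, m1$n)
  delta[defined] <- (m2$values[defined] - m1$values[defined]) / m1$values[defined]
  structure(list(metric = m1$metric, delta = delta, defined = defined,
                 n = m1$n), class = "delta_metric")
}

#' @export
print.delta_metric <- function(x, ...) {
  cat(sprintf("<delta_metric> %s: %d/%d nodes defined, mean |dM| %.4g\n",
              x$metric, sum(x$defined), x$n,
              mean(abs(x$delta[x$defined]))))
  invisible(x)
}

#' Display filter: keep only prominent changes
#'
#' A node is shown when its absolute relative change exceeds half the mean
#' absolute change over all defined nodes.  The mean is taken over absolute
#' values; a signed mean could be negative and would then hide nothing.
#'
#' @param delta a [delta_metric()] object.
#' @return logical vector, `TRUE` for shown nodes (`FALSE` at undefined
#'   nodes); attribute `threshold` records the cut value.
#' @export
display_filter <- function(delta) {
  stopifnot(inherits(delta, "delta_metric"))
  if (!any(delta$defined)) {
    warning("no defined relative changes; nothing to show")
    return(structure(rep(FALSE, delta$n), threshold = NA_real_))
  }
  thr <- 0.5 * mean(abs(delta$delta[delta$defined]))
  shown <- delta$defined & abs(delta$delta) > thr
  shown[is.na(shown)] <- FALSE
  structure(shown, threshold = thr)
}

#' Aggregate shown node changes into per-region summaries
#'
#' For every (region, side) with at least one shown node, reports the
#' direction tags present (a region showing both increasing and decreasing
#' nodes carries both tags), the contributing node ids, and the mean relative
#' change over its shown nodes.
#'
#' @param delta a [delta_metric()] object.
#' @param map node-region map from [assign_nodes_to_regions()] whose rows
#'   align with the delta's node order.
#' @param shown logical vector from [display_filter()].
#' @return data.frame: `region, abbreviation, side, increase, decrease,
#'   n_nodes, node_ids, mean_delta`; attribute `n_unmapped_shown` counts shown
#'   nodes that had no region.
#' @export
region_aggregate <- function(delta, map, shown = display_filter(delta)) {
  stopifnot(inherits(delta, "delta_metric"), nrow(map) == delta$n)
  idx <- which(shown & map$mapped)
  n_unmapped <- sum(shown & !map$mapped)
  if (length(idx) == 0) {
    out <- data.frame(region = character(), abbreviation = character(),
                      side = character(), increase = logical(),
                      decrease = logical(), n_nodes = integer(),
                      node_ids = character(), mean_delta = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "n_unmapped_shown") <- n_unmapped
    return(out)
  }
  key <- paste(map$region[idx], map$side[idx], sep = "|")
  rows <- lapply(split(idx, key), function(ii) {
    data.frame(region = map$region[ii[1]],
               abbreviation = map$abbreviation[ii[1]],
               side = map$side[ii[1]],
               increase = any(delta$delta[ii] > 0),
               decrease = any(delta$delta[ii] < 0),
               n_nodes = length(ii),
               node_ids = paste(map$node_id[ii], collapse = ";"),
               mean_delta = mean(delta$delta[ii]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$side, out$region), , drop = FALSE]
  attr(out, "n_unmapped_shown") <- n_unmapped
  out
}

#' Split a region summary by hemisphere
#'
#' With lesions normalised to the right hemisphere, nodes at `x > 0` are
#' ipsilesional (IL) and `x < 0` contralesional (CL); exact midline nodes are
#' excluded from both and counted.  The split keys on the sign of each
#' contributing node's x-coordinate.
#'
#' @param summary region summary from [region_aggregate()].
#' @param nodes node table aligned with the original node ids.
#' @return list with elements `IL`, `CL` (region summaries) and
#'   `n_midline` (count of midline contributing nodes).
#' @export
hemisphere_split <- function(summary, nodes) {
  hemi_of <- stats::setNames(node_hemisphere(nodes), nodes$node_id)
  pick <- function(label) {
    keep <- vapply(strsplit(summary$node_ids, ";"), function(ids) {
      any(hemi_of[ids] == label)
    }, logical(1))
    summary[keep, , drop = FALSE]
  }
  all_ids <- unlist(strsplit(summary$node_ids, ";"))
  list(IL = pick("IL"), CL = pick("CL"),
       n_midline = sum(hemi_of[all_ids] == "midline"))
}
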