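#' Node tables, hemisphere flipping, and anatomical attribution
#'
#' Nodes are points in MNI millimetre space.  Each node is attributed to the
#' anatomical (AAL) region owning the Euclidean-nearest coordinate in a
#' packaged region table; nodes farther than a cap distance from every listed
#' coordinate stay explicitly unattributed.  Lesions are normalised to the
#' right hemisphere by mirroring node x-coordinates.
#'
#' @name atlas
NULL

#' Load a node-coordinate table
#'
#' Reads a delimited file with columns `node_id, x, y, z` (comma or tab
#' separated, autodetected).  Row order defines the node index order used by
#' the time-series matrices.
#'
#' @param path file path.
#' @return data.frame with columns `node_id, x, y, z`.
#' @export
load_node_table <- function(path) {
  if (!file.exists(path)) stop("node table not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("node table is empty: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_node_table(df)
}

#' Validate a node table
#'
#' @param df data.frame with columns `node_id, x, y, z`.
#' @return the validated data.frame (row order preserved).
#' @export
validate_node_table <- function(df) {
  need <- c("node_id", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("node table must have columns node_id, x, y, z", call. = FALSE)
  }
  if (nrow(df) == 0) stop("node table has no rows", call. = FALSE)
  for (cn in c("x", "y", "z")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
    if (length(bad)) {
      stop(sprintf("non-numeric %s coordinate at row(s): %s", cn,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    df[[cn]] <- as.numeric(df[[cn]])
  }
  dup <- df$node_id[duplicated(df$node_id)]
  if (length(dup)) {
    stop("duplicate node id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  df[, need]
}

#' Load the packaged anatomical region table
#'
#' One row per listed region coordinate (columns
#' `region, abbreviation, side, x, y, z`); entries the source table marks with
#' a dash carry `NA` coordinates and act as an empty coordinate list.
#'
#' @param path optional path to an alternative table with the same columns;
#'   defaults to the packaged transcription.
#' @return data.frame.
#' @export
load_region_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aal_regions.csv", package = "strokenet")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "abbreviation", "side", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("region table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$side %in% c("Left", "Right"))) {
    stop("region side must be Left or Right", call. = FALSE)
  }
  df
}

#' Mirror a node table so the lesion sits in the right hemisphere
#'
#' For a left-lesion subject every x-coordinate changes sign (left/right
#' swap); right-lesion subjects pass through unchanged.  y and z are never
#' touched, and applying the flip twice restores the original table.
#'
#' @param nodes node table (see [load_node_table()]).
#' @param lesion_side `"Left"` or `"Right"`.
#' @return node table with possibly mirrored x.
#' @export
flip_lesion_to_right <- function(nodes, lesion_side) {
  if (!is.character(lesion_side) || length(lesion_side) != 1 ||
      !lesion_side %in% c("Left", "Right")) {
    stop("lesion_side must be \"Left\" or \"Right\"", call. = FALSE)
  }
  if (lesion_side == "Left") nodes$x <- -nodes$x
  nodes
}

#' Attribute nodes to anatomical regions by nearest coordinate
#'
#' Each node maps to the (region, side) owning the Euclidean-nearest
#' coordinate in the region table; distance ties go to the earlier region-table
#' row.  Nodes whose nearest listed coordinate is farther than `max_distance`
#' millimetres are flagged unmapped rather than force-assigned.
#'
#' @param nodes node table.
#' @param regions region table (see [load_region_table()]).
#' @param max_distance attribution cap in mm (default 15).
#' @return data.frame with one row per node: `node_id, region, abbreviation,
#'   side, distance, mapped`.
#' @export
assign_nodes_to_regions <- function(nodes, regions, max_distance = 15) {
  nodes <- validate_node_table(nodes)
  regions <- regions[is.finite(regions$x), , drop = FALSE]
  if (nrow(regions) == 0) stop("region table has no coordinates", call. = FALSE)
  np <- as.matrix(nodes[, c("x", "y", "z")])
  rp <- as.matrix(regions[, c("x", "y", "z")])
  # squared distances node x coordinate, vectorised
  d2 <- outer(rowSums(np^2), rowSums(rp^2), "+") - 2 * np %*% t(rp)
  d2[d2 < 0] <- 0
  nearest <- apply(d2, 1, which.min)      # first minimum = table row order
  dist <- sqrt(d2[cbind(seq_len(nrow(np)), nearest)])
  mapped <- dist <= max_distance
  data.frame(node_id = nodes$node_id,
             region = ifelse(mapped, regions$region[nearest], NA_character_),
             abbreviation = ifelse(mapped, regions$abbreviation[nearest],
                                   NA_character_),
             side = ifelse(mapped, regions$side[nearest], NA_character_),
             distance = dist, mapped = mapped, stringsAsFactors = FALSE)
}

#' Default region-of-interest composition for the motor analysis
#'
#' Three ROIs built from region-table abbreviations: primary sensorimotor
#' cortex (precentral + postcentral gyri), supplementary motor area (medial
#' frontal gyrus nodes), and premotor cortex (superior + middle frontal gyri).
#' The composition is an interpretation and fully configurable — pass any
#' named list of abbreviation vectors to [roi_node_sets()].
#'
#' @return named list of abbreviation character vectors.
#' @export
default_roi_spec <- function() {
  list(SM1 = c("PrCG", "PoCG"),
       SMA = "MlFG",
       PM  = c("SFG", "MFG"))
}

#' Resolve ROI specifications to per-side node-id sets
#'
#' @param map node-region map from [assign_nodes_to_regions()].
#' @param roi_spec named list: ROI name -> character vector of region-table
#'   abbreviations (default [default_roi_spec()]).
#' @return nested list `roi -> list(Left = ids, Right = ids)`; empty ROIs are
#'   kept (with a warning) so downstream code can report them as missing.
#' @export
roi_node_sets <- function(map, roi_spec = default_roi_spec()) {
  if (length(roi_spec) == 0) return(list())
  out <- list()
  for (roi in names(roi_spec)) {
    abbr <- roi_spec[[roi]]
    unknown <- setdiff(abbr, map$abbreviation[map$mapped])
    sides <- list()
    for (side in c("Left", "Right")) {
      ids <- map$node_id[map$mapped & map$side == side &
                           map$abbreviation %in% abbr]
      if (length(ids) == 0) {
        warning(sprintf("ROI %s has no %s-side nodes%s", roi, side,
                        if (length(unknown))
                          paste0(" (unknown abbreviation: ",
                                 paste(unknown, collapse = ", "), ")")
                        else ""), call. = FALSE)
      }
      sides[[side]] <- ids
    }
    out[[roi]] <- sides
  }
  out
}

#' Hemisphere label of each node after lesion normalisation
#'
#' With all lesions flipped to the right hemisphere, `x > 0` is ipsilesional
#' (IL), `x < 0` contralesional (CL), and exact midline nodes belong to
#' neither.
#'
#' @param nodes node table (post-flip).
#' @return character vector `"IL"`, `"CL"` or `"midline"` per node.
#' @export
node_hemisphere <- function(nodes) {
  ifelse(nodes$x > 0, "IL", ifelse(nodes$x < 0, "CL", "midline"))
}
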