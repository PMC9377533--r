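#' Clinical scores and the brain-behaviour correlation analysis
#'
#' Group assignment from first-session Rankin/Barthel scores, Fugl-Meyer
#' change scores, ROI-averaged betweenness change, and the per-ROI Pearson
#' correlation between average betweenness change and upper-extremity
#' Fugl-Meyer improvement.
#'
#' @name clinical
NULL

#' Assign subjects to the motor-impaired or control group
#'
#' Classification uses the first-session scores: control requires Rankin 0 or
#' 1 together with Barthel 100; motor impairment requires Rankin >= 1 together
#' with Barthel < 100.  Combinations covered by neither rule (e.g. Rankin 0
#' with Barthel < 100) are surfaced as `"unclassified"` rather than binned.
#'
#' @param rankin_t1 integer Rankin score(s) 0..5 at the first assessment.
#' @param barthel_t1 Barthel index 0..100 at the first assessment.
#' @return character vector: `"motor"`, `"control"` or `"unclassified"`.
#' @export
assign_group <- function(rankin_t1, barthel_t1) {
  if (anyNA(rankin_t1) || anyNA(barthel_t1)) {
    stop("Rankin and Barthel scores are required for group assignment",
         call. = FALSE)
  }
  if (any(!rankin_t1 %in% 0:5) || any(barthel_t1 < 0 | barthel_t1 > 100)) {
    stop("Rankin must be in 0..5 and Barthel in 0..100", call. = FALSE)
  }
  ifelse(rankin_t1 %in% c(0, 1) & barthel_t1 == 100, "control",
         ifelse(rankin_t1 >= 1 & barthel_t1 < 100, "motor", "unclassified"))
}

#' Upper-extremity Fugl-Meyer change score
#'
#' @param uefm_t1,uefm_t2 scores on the 0-66 upper-extremity scale at the two
#'   assessments.
#' @return `uefm_t2 - uefm_t1`, in points.
#' @export
delta_uefm <- function(uefm_t1, uefm_t2) {
  if (anyNA(uefm_t1) || anyNA(uefm_t2)) {
    stop("both UE-FM scores are required", call. = FALSE)
  }
  if (any(uefm_t1 < 0 | uefm_t1 > 66 | uefm_t2 < 0 | uefm_t2 > 66)) {
    stop("UE-FM scores must lie in 0..66", call. = FALSE)
  }
  uefm_t2 - uefm_t1
}

#' ROI-averaged betweenness change for one subject
#'
#' Arithmetic mean of the relative betweenness change over the ROI's nodes,
#' after removing nodes whose change is undefined (zero baseline).  An ROI
#' with no defined node yields `NA` with attribute `empty = TRUE` so the
#' subject can be dropped listwise by the correlation step.
#'
#' @param delta a `"BC"` [delta_metric()].
#' @param roi_nodes integer node indices (positions in the delta's node
#'   order).
#' @return scalar mean change, or flagged `NA`.
#' @export
roi_mean_delta_bc <- function(delta, roi_nodes) {
  stopifnot(inherits(delta, "delta_metric"))
  roi_nodes <- roi_nodes[roi_nodes >= 1 & roi_nodes <= delta$n]
  ok <- roi_nodes[delta$defined[roi_nodes]]
  if (length(ok) == 0) {
    return(structure(NA_real_, empty = TRUE))
  }
  mean(delta$delta[ok])
}

#' Correlate ROI-averaged metric change with a clinical change score
#'
#' Pearson correlation (default) with the exact two-sided p-value from the
#' t transform with n-2 degrees of freedom; pairs with a missing value in
#' either variable are dropped listwise.  No multiple-comparison correction is
#' applied by default; `correction = "holm"` adjusts across a family when
#' called through [run_fig5_analysis()].
#'
#' @param deltas per-subject mean metric changes.
#' @param scores per-subject clinical change scores, same order.
#' @param alpha significance level (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param roi,hemisphere optional labels carried into the result.
#' @return one-row data.frame: `roi, hemisphere, n, r, p, significant`.
#' @export
correlate_roi <- function(deltas, scores, alpha = 0.05,
                          method = c("pearson", "spearman"),
                          roi = NA_character_, hemisphere = NA_character_) {
  method <- match.arg(method)
  if (length(deltas) != length(scores)) {
    stop("deltas and scores must have the same length", call. = FALSE)
  }
  ok <- is.finite(deltas) & is.finite(scores)
  x <- deltas[ok]; y <- scores[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant variable", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  data.frame(roi = roi, hemisphere = hemisphere, n = n, r = r, p = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' ROI x hemisphere correlation panel
#'
#' Runs the full brain-behaviour analysis for the motor group: for each of
#' three ROIs (primary sensorimotor, supplementary motor, premotor) and each
#' hemisphere (CL = left side after lesion normalisation, IL = right side),
#' correlates the subjects' ROI-averaged betweenness change with their UE-FM
#' change.  Subjects missing either quantity in a panel are dropped from that
#' panel (listwise).
#'
#' @param bc_deltas named list, one `"BC"` [delta_metric()] per subject.
#' @param roi_sets per-subject ROI node sets: either one shared
#'   `roi -> list(Left, Right)` structure from [roi_node_sets()], or a named
#'   list of such structures keyed by subject id.
#' @param clinical data.frame with columns `subject_id, uefm_t1, uefm_t2`
#'   restricted to the motor group.
#' @param alpha significance level (default 0.05).
#' @param method correlation type, see [correlate_roi()].
#' @param correction `"none"` (default) or `"holm"` across the 6 panels.
#' @return data.frame of 6 rows (`roi, hemisphere, n, r, p, significant`);
#'   attribute `scatter` holds the per-panel subject-level points.
#' @export
run_fig5_analysis <- function(bc_deltas, roi_sets, clinical, alpha = 0.05,
                              method = "pearson",
                              correction = c("none", "holm")) {
  correction <- match.arg(correction)
  subjects <- clinical$subject_id
  if (is.null(names(bc_deltas)) || !all(subjects %in% names(bc_deltas))) {
    stop("bc_deltas must be named by subject id and cover the clinical table",
         call. = FALSE)
  }
  per_subject_sets <- !is.null(names(roi_sets)) &&
    all(subjects %in% names(roi_sets))
  duefm <- delta_uefm(clinical$uefm_t1, clinical$uefm_t2)
  hemi_side <- c(CL = "Left", IL = "Right")
  roi_names <- names(if (per_subject_sets) roi_sets[[1]] else roi_sets)
  results <- list()
  scatter <- list()
  for (roi in roi_names) {
    for (hemi in names(hemi_side)) {
      mdbc <- vapply(seq_along(subjects), function(si) {
        sets <- if (per_subject_sets) roi_sets[[subjects[si]]] else roi_sets
        ids <- sets[[roi]][[hemi_side[[hemi]]]]
        if (length(ids) == 0) return(NA_real_)
        as.numeric(roi_mean_delta_bc(bc_deltas[[subjects[si]]], ids))
      }, numeric(1))
      res <- tryCatch(
        correlate_roi(mdbc, duefm, alpha = alpha, method = method,
                      roi = roi, hemisphere = hemi),
        error = function(e) {
          warning(sprintf("panel %s/%s not testable: %s", roi, hemi,
                          conditionMessage(e)), call. = FALSE)
          data.frame(roi = roi, hemisphere = hemi,
                     n = sum(is.finite(mdbc) & is.finite(duefm)),
                     r = NA_real_, p = NA_real_, significant = NA,
                     stringsAsFactors = FALSE)
        })
      results[[paste(roi, hemi)]] <- res
      ok <- is.finite(mdbc) & is.finite(duefm)
      if (any(ok)) {
        scatter[[paste(roi, hemi)]] <- data.frame(
          roi = roi, hemisphere = hemi, subject_id = subjects[ok],
          mean_delta_bc = mdbc[ok], delta_uefm = duefm[ok],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  if (correction == "holm") {
    out$p <- stats::p.adjust(out$p, method = "holm")
    out$significant <- out$p < alpha
  }
  attr(out, "scatter") <- do.call(rbind, scatter)
  out
}
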