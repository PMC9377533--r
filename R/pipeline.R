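#' End-to-end orchestration and command-line entry points
#'
#' The pipeline runs, in order: scrubbing exclusion, pre-whitening, Pearson
#' connectivity, proportional thresholding, node metrics per session,
#' relative change, display filtering, anatomical aggregation, and the
#' ROI x hemisphere brain-behaviour correlation.  Configuration is one JSON
#' document; every stage's output is persisted as plain CSV plus a
#' machine-readable JSON run log.
#'
#' @name pipeline
NULL

#' Pipeline options
#'
#' @param density edge density kept by proportional thresholding (default 0.20).
#' @param mode correlation ranking, `"signed"` or `"absolute"`.
#' @param cpl_policy `"reachable"` or `"literal"` (see [char_path_length()]).
#' @param alpha significance level of the correlation panels (default 0.05).
#' @param correction `"none"` or `"holm"` across the 6 panels.
#' @param prewhiten logical; run AR pre-whitening before correlation.
#' @param max_order maximum AR order for pre-whitening (default 10).
#' @param scrub_limit discarded-volume exclusion threshold (default 30).
#' @param max_distance anatomical attribution cap in mm (default 15).
#' @param roi_spec named list of ROI compositions (default [default_roi_spec()]).
#' @param cor_method `"pearson"` or `"spearman"`.
#' @return list of class `pipeline_options`.
#' @export
pipeline_options <- function(density = 0.20, mode = "signed",
                             cpl_policy = "reachable", alpha = 0.05,
                             correction = "none", prewhiten = TRUE,
                             max_order = 10, scrub_limit = 30,
                             max_distance = 15,
                             roi_spec = default_roi_spec(),
                             cor_method = "pearson") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(list(density = density, mode = mode, cpl_policy = cpl_policy,
                 alpha = alpha, correction = correction,
                 prewhiten = prewhiten, max_order = max_order,
                 scrub_limit = scrub_limit, max_distance = max_distance,
                 roi_spec = roi_spec, cor_method = cor_method),
            class = "pipeline_options")
}

#' Align a cohort to lesion-right space
#'
#' Mimics the upstream image flipping at node level: for every left-lesion
#' subject, node signals are permuted by the x-mirror partner map of the node
#' table, so that after alignment all subjects' column `i` carries the signal
#' of the same anatomical location in lesion-right space and the unflipped
#' node table applies to everyone.  Requires an exactly mirror-symmetric node
#' table (e.g. [synthetic_node_table()]); with an asymmetric table the series
#' are left untouched with a warning and only coordinate-level flipping
#' ([flip_lesion_to_right()]) is available.
#'
#' @param cohort an `fc_cohort` (or list with `series`, `clinical`,
#'   `node_table`).
#' @return the cohort with permuted series and a `flipped_subjects`
#'   attribute.
#' @export
align_cohort_to_lesion_right <- function(cohort) {
  twins <- mirror_partners(cohort$node_table)
  flipped <- character()
  left <- cohort$clinical$subject_id[cohort$clinical$lesion_side == "Left"]
  if (length(left) && anyNA(twins)) {
    warning("node table is not mirror-symmetric; series left unflipped")
    return(structure(cohort, flipped_subjects = flipped))
  }
  for (sid in left) {
    for (ses in c("session1", "session2")) {
      s <- cohort$series[[sid]][[ses]]
      cohort$series[[sid]][[ses]] <- s[, twins, drop = FALSE]
      colnames(cohort$series[[sid]][[ses]]) <- colnames(s)
    }
    flipped <- c(flipped, sid)
  }
  structure(cohort, flipped_subjects = flipped)
}

# connectivity + binary graph + metrics + per-metric deltas for one subject
subject_pipeline <- function(s1, s2, opts) {
  if (opts$prewhiten) {
    s1 <- prewhiten(s1, opts$max_order)
    s2 <- prewhiten(s2, opts$max_order)
  }
  c1 <- pearson_matrix(s1); c2 <- pearson_matrix(s2)
  a1 <- proportional_threshold(c1, opts$density, opts$mode)
  a2 <- proportional_threshold(c2, opts$density, opts$mode)
  m1 <- all_metrics(a1, opts$cpl_policy)
  m2 <- all_metrics(a2, opts$cpl_policy)
  deltas <- lapply(stats::setNames(names(m1), names(m1)),
                   function(m) delta_metric(m1[[m]], m2[[m]]))
  list(conn = list(c1, c2), adj = list(a1, a2),
       metrics = list(m1, m2), deltas = deltas)
}

#' Run the full analysis pipeline on a cohort
#'
#' @param cohort an `fc_cohort` from [simulate_cohort()] or assembled from
#'   disk by [read_cohort_dir()].
#' @param opts a [pipeline_options()] object.
#' @param region_table anatomical region table (default packaged).
#' @return list of class `fc_results` with components `included`, `excluded`,
#'   `groups`, `subject` (per-subject connectivity/metrics/deltas),
#'   `group_deltas` (deltas of the group-average graphs), `region_summaries`,
#'   `correlations`, `map`, `roi_sets`, `log`.
#' @export
run_pipeline <- function(cohort, opts = pipeline_options(),
                         region_table = load_region_table()) {
  log <- list()

  # 1. scrubbing exclusion: any session above the limit excludes the subject
  verdict <- tapply(scrub_check(cohort$scrub$censored_volumes,
                                opts$scrub_limit),
                    cohort$scrub$subject_id, function(v) any(v == "exclude"))
  excluded <- names(verdict)[verdict]
  included <- setdiff(cohort$clinical$subject_id, excluded)
  if (length(included) == 0) stop("all subjects excluded by scrubbing", call. = FALSE)
  log$excluded_by_scrubbing <- excluded

  # 2. lesion normalisation (node-level analogue of image flipping)
  cohort <- align_cohort_to_lesion_right(cohort)
  log$flipped_subjects <- attr(cohort, "flipped_subjects")

  # 3. group assignment round-trip from the clinical scores
  clin <- cohort$clinical[cohort$clinical$subject_id %in% included, ]
  clin$group_assigned <- assign_group(clin$rankin_t1, clin$barthel_t1)
  log$unclassified <- clin$subject_id[clin$group_assigned == "unclassified"]

  # 4. per-subject connectivity, metrics, deltas
  subject <- list()
  for (sid in included) {
    subject[[sid]] <- subject_pipeline(cohort$series[[sid]]$session1,
                                       cohort$series[[sid]]$session2, opts)
  }
  log$ties_at_cutoff <- vapply(subject, function(s)
    attr(s$adj[[1]], "n_ties_at_cutoff"), integer(1))

  # 5. anatomical attribution on the shared (lesion-right) node table
  map <- assign_nodes_to_regions(cohort$node_table, region_table,
                                 opts$max_distance)
  log$unmapped_nodes <- sum(!map$mapped)
  roi_sets <- suppressWarnings(roi_node_sets(map, opts$roi_spec))
  roi_pos <- lapply(roi_sets, function(r) lapply(r, function(ids)
    match(ids, cohort$node_table$node_id)))

  # 6. group-average graphs and their relative changes
  groups <- split(clin$subject_id, clin$group_assigned)
  group_deltas <- list(); region_summaries <- list()
  for (g in names(groups)) {
    if (length(groups[[g]]) == 0) next
    avg <- lapply(1:2, function(ses) group_average(
      lapply(groups[[g]], function(sid) subject[[sid]]$conn[[ses]])))
    adjs <- lapply(avg, proportional_threshold,
                   density = opts$density, mode = opts$mode)
    ms <- lapply(adjs, all_metrics, cpl_policy = opts$cpl_policy)
    gd <- lapply(stats::setNames(names(ms[[1]]), names(ms[[1]])),
                 function(m) delta_metric(ms[[1]][[m]], ms[[2]][[m]]))
    group_deltas[[g]] <- gd
    region_summaries[[g]] <- lapply(gd, function(d) {
      shown <- display_filter(d)
      summ <- region_aggregate(d, map, shown)
      summ$hemisphere <- ifelse(summ$side == "Right", "IL", "CL")
      summ
    })
  }

  # 7. brain-behaviour correlation panels for the motor group
  correlations <- NULL
  motor <- intersect(groups$motor, clin$subject_id[!is.na(clin$uefm_t1)])
  if (length(motor) >= 3) {
    bc_deltas <- lapply(stats::setNames(motor, motor),
                        function(sid) subject[[sid]]$deltas$BC)
    correlations <- run_fig5_analysis(
      bc_deltas, roi_pos, clin[match(motor, clin$subject_id), ],
      alpha = opts$alpha, method = opts$cor_method,
      correction = opts$correction)
  } else {
    log$correlation_skipped <- "fewer than 3 motor-group subjects"
  }

  structure(list(included = included, excluded = excluded,
                 groups = groups, subject = subject,
                 group_deltas = group_deltas,
                 region_summaries = region_summaries,
                 correlations = correlations, map = map,
                 roi_sets = roi_sets, clinical = clin, log = log,
                 options = opts, node_table = cohort$node_table),
            class = "fc_results")
}

#' Read one subject-session time-series file
#'
#' Tab- or comma-separated, T rows x N columns with a header row of node ids.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_time_series <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                   check.names = FALSE))
  if (anyNA(m)) stop("missing values in time series: ", path, call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `*_ses-*_timeseries.tsv`, `clinical.csv`,
#'   `nodes.csv` and optionally `scrub.csv`.
#' @return an `fc_cohort`-shaped list.
#' @export
read_cohort_dir <- function(dir) {
  files <- list.files(dir, pattern = "_ses-[12]_timeseries\\.tsv$",
                      full.names = TRUE)
  if (length(files) == 0) {
    stop("no time-series files found in ", dir, call. = FALSE)
  }
  sids <- unique(sub("_ses-[12]_timeseries\\.tsv$", "", basename(files)))
  series <- list()
  for (sid in sids) {
    series[[sid]] <- list(
      session1 = read_time_series(file.path(
        dir, sprintf("%s_ses-1_timeseries.tsv", sid))),
      session2 = read_time_series(file.path(
        dir, sprintf("%s_ses-2_timeseries.tsv", sid))))
    if (ncol(series[[sid]]$session1) != ncol(series[[sid]]$session2)) {
      stop("node count differs between sessions for ", sid, call. = FALSE)
    }
  }
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  node_table <- validate_node_table(
    utils::read.csv(file.path(dir, "nodes.csv"), stringsAsFactors = FALSE))
  scrub_path <- file.path(dir, "scrub.csv")
  scrub <- if (file.exists(scrub_path)) {
    utils::read.csv(scrub_path, stringsAsFactors = FALSE)
  } else {
    data.frame(subject_id = rep(sids, each = 2), session = rep(1:2, length(sids)),
               censored_volumes = 0, stringsAsFactors = FALSE)
  }
  structure(list(series = series, clinical = clinical, scrub = scrub,
                 node_table = node_table), class = "fc_cohort")
}

#' Persist pipeline results as a plain-text results tree
#'
#' @param results an `fc_results` from [run_pipeline()].
#' @param out_dir output directory.
#' @return invisibly, the manifest as a list.
#' @export
write_results <- function(results, out_dir) {
  dir.create(file.path(out_dir, "metrics"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "delta"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "group"), showWarnings = FALSE)
  for (sid in names(results$subject)) {
    sp <- results$subject[[sid]]
    for (ses in 1:2) {
      for (m in names(sp$metrics[[ses]])) {
        utils::write.csv(metrics_to_df(sp$metrics[[ses]][m], sid, ses),
                         file.path(out_dir, "metrics",
                                   sprintf("%s_ses-%d_%s.csv", sid, ses, m)),
                         row.names = FALSE)
      }
    }
    dd <- do.call(rbind, lapply(names(sp$deltas), function(m) {
      d <- sp$deltas[[m]]
      shown <- display_filter(d)
      data.frame(subject_id = sid, metric = m, node_id = seq_len(d$n),
                 delta = d$delta, defined = d$defined, shown = shown,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(dd, file.path(out_dir, "delta", paste0(sid, ".csv")),
                     row.names = FALSE)
  }
  for (g in names(results$region_summaries)) {
    rs <- do.call(rbind, lapply(names(results$region_summaries[[g]]),
      function(m) {
        s <- results$region_summaries[[g]][[m]]
        if (nrow(s)) cbind(metric = m, s) else NULL
      }))
    if (!is.null(rs)) {
      utils::write.csv(rs, file.path(out_dir, "group",
                                     paste0(g, "_region_summary.csv")),
                       row.names = FALSE)
    }
    gd <- do.call(rbind, lapply(names(results$group_deltas[[g]]), function(m) {
      d <- results$group_deltas[[g]][[m]]
      data.frame(group = g, metric = m, node_id = seq_len(d$n),
                 delta = d$delta, defined = d$defined,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(gd, file.path(out_dir, "group", paste0(g, "_delta.csv")),
                     row.names = FALSE)
  }
  if (!is.null(results$correlations)) {
    utils::write.csv(results$correlations,
                     file.path(out_dir, "correlations.csv"), row.names = FALSE)
    utils::write.csv(attr(results$correlations, "scatter"),
                     file.path(out_dir, "scatter.csv"), row.names = FALSE)
  }
  utils::write.csv(results$map, file.path(out_dir, "node_region_map.csv"),
                   row.names = FALSE)
  manifest <- list(included = results$included, excluded = results$excluded,
                   options = unclass(results$options), log = results$log)
  jsonlite::write_json(manifest, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- substring(names(manifest$checksums),
                                         nchar(out_dir) + 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a cohort and write it to disk
#'
#' @param config a [simulation_config()], or a path to a JSON document whose
#'   keys override [simulation_config()] defaults.
#' @param out_dir output directory.
#' @return invisibly, the manifest list (config, seeds, file checksums).
#' @export
cmd_simulate <- function(config = simulation_config(), out_dir) {
  if (is.character(config)) config <- load_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  cohort <- simulate_cohort(config)
  paths <- write_cohort(cohort, out_dir)
  manifest <- list(
    config = unclass(config),
    subject_seeds = stats::setNames(
      config$seed + 7919L * seq_along(cohort$series), names(cohort$series)),
    target_nodes = cohort$target_nodes,
    checksums = as.list(tools::md5sum(paths)))
  names(manifest$checksums) <- basename(paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a simulation configuration from a JSON document
#'
#' Unknown keys raise an error naming the key.
#'
#' @param path JSON file path.
#' @return a [simulation_config()].
#' @export
load_sim_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(simulation_config, cfg)
}

#' Run the full pipeline from a cohort directory
#'
#' @param input_dir cohort directory (see [read_cohort_dir()]).
#' @param out_dir results directory.
#' @param opts a [pipeline_options()].
#' @param region_table optional region-table path.
#' @return invisibly, the `fc_results`.
#' @export
cmd_run <- function(input_dir, out_dir, opts = pipeline_options(),
                    region_table = NULL) {
  cohort <- read_cohort_dir(input_dir)
  rt <- if (is.null(region_table)) load_region_table()
        else load_region_table(region_table)
  results <- run_pipeline(cohort, opts, rt)
  write_results(results, out_dir)
  invisible(results)
}

#' Command-line dispatcher
#'
#' Subcommands: `simulate` (write a synthetic cohort), `run` (full pipeline),
#' `report` (summarise a results manifest).  Used by the packaged executable
#' script `inst/cli/strokenet`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
strokenet_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: strokenet <simulate|run|report> [options]\n"
  if (length(args) < 1) { cat(usage); return(invisible(1L)) }
  cmd <- args[1]; rest <- args[-1]
  getopt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) == 1 && i < length(rest)) rest[i + 1] else default
  }
  if (cmd == "simulate") {
    cfg_path <- getopt("--config")
    out <- getopt("--out", "cohort")
    seed <- getopt("--seed")
    cfg <- if (is.null(cfg_path)) simulation_config()
           else load_sim_config(cfg_path)
    if (!is.null(seed)) {
      cfg <- do.call(simulation_config,
                     utils::modifyList(unclass(cfg)[names(formals(simulation_config))],
                                       list(seed = as.integer(seed))))
    }
    cmd_simulate(cfg, out)
    cat("cohort written to ", out, "\n", sep = "")
  } else if (cmd == "run") {
    input <- getopt("--input")
    out <- getopt("--out", "results")
    if (is.null(input)) stop("run needs --input <cohort dir>", call. = FALSE)
    opts <- pipeline_options(
      density = as.numeric(getopt("--density", "0.20")),
      mode = getopt("--mode", "signed"),
      alpha = as.numeric(getopt("--alpha", "0.05")),
      correction = getopt("--correction", "none"),
      cpl_policy = getopt("--cpl-policy", "reachable"))
    cmd_run(input, out, opts)
    cat("results written to ", out, "\n", sep = "")
  } else if (cmd == "report") {
    path <- getopt("--manifest", "results/manifest.json")
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    cat("included subjects: ", paste(m$included, collapse = ", "), "\n",
        "excluded subjects: ", paste(m$excluded, collapse = ", "), "\n",
        "files: ", length(m$checksums), "\n", sep = "")
  } else {
    cat(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
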