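#' Synthetic two-session cohort generator
#'
#' Emulates the statistical structure the downstream analysis assumes: per
#' subject, two sessions of T x N node time series with AR(1) temporal
#' autocorrelation and a block latent-factor ("modular") spatial covariance;
#' a clinical table with Rankin/Barthel/NIHSS/Fugl-Meyer scores that
#' round-trips through [assign_group()]; and, in session 2, a plantable hub
#' shift that turns a set of target nodes into inter-community bridges, with
#' magnitude coupled to the subject's simulated upper-extremity Fugl-Meyer
#' recovery.
#'
#' @name synthetic-data
NULL

# run expr under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Defaults mirror the study design being emulated: 264 functional-atlas
#' nodes, 180 time points at TR = 2 s, 6 motor-impaired and 7 control
#' subjects.  Magnitude parameters of the planted effect (`effect_strength`,
#' `behavior_coupling`) are free parameters of the simulation, not estimates
#' of any empirical effect size.
#'
#' @param n_nodes number of nodes (default 264).
#' @param n_timepoints time points per session (default 180).
#' @param tr repetition time in seconds (metadata only, default 2).
#' @param n_motor,n_control group sizes (defaults 6 and 7).
#' @param module_partition integer community label per node; the default
#'   assigns consecutive node pairs (mirror twins in synthetic node tables)
#'   to the same community, cycling through
#'   `max(2, min(10, n_nodes %/% 8))` communities.
#' @param ar_coefficient AR(1) coefficient of factors and noise, in (-1, 1)
#'   (default 0.4).
#' @param noise_sd marginal standard deviation of node-specific noise
#'   (default 1; community factors have unit scale).
#' @param target_nodes node indices receiving the session-2 hub shift;
#'   `NULL` (default) lets [simulate_cohort()] target the contralesional
#'   primary-sensorimotor nodes of the synthetic node table.
#' @param effect_strength non-negative scale of the hub shift (default 1).
#' @param behavior_coupling in \[0, 1\]: 1 ties the hub-shift magnitude
#'   deterministically to the simulated UE-FM recovery, 0 decouples them
#'   (default 0.8).
#' @param seed master seed; per-subject streams are derived by fixed offsets.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(n_nodes = 264, n_timepoints = 180, tr = 2,
                              n_motor = 6, n_control = 7,
                              module_partition = NULL,
                              ar_coefficient = 0.4, noise_sd = 1,
                              target_nodes = NULL, effect_strength = 1,
                              behavior_coupling = 0.8, seed = 1) {
  if (n_nodes < 3 || n_timepoints < 10) {
    stop("need n_nodes >= 3 and n_timepoints >= 10", call. = FALSE)
  }
  if (n_motor < 0 || n_control < 0 || n_motor + n_control < 2) {
    stop("need n_motor + n_control >= 2 with non-negative sizes", call. = FALSE)
  }
  if (abs(ar_coefficient) >= 1) {
    stop("ar_coefficient must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (effect_strength < 0) stop("effect_strength must be >= 0", call. = FALSE)
  if (behavior_coupling < 0 || behavior_coupling > 1) {
    stop("behavior_coupling must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (is.null(module_partition)) {
    # consecutive node pairs share a community: synthetic node tables place
    # mirror twins at positions (2k-1, 2k), and homotopic regions belonging
    # to the same functional system is the realistic default
    k <- max(2, min(10, n_nodes %/% 8))
    module_partition <- ((ceiling(seq_len(n_nodes) / 2) - 1) %% k) + 1
  }
  if (length(module_partition) != n_nodes) {
    stop("module_partition must assign every node", call. = FALSE)
  }
  if (!is.null(target_nodes)) {
    target_nodes <- as.integer(target_nodes)
    if (any(target_nodes < 1 | target_nodes > n_nodes)) {
      stop("target_nodes outside 1..n_nodes", call. = FALSE)
    }
  }
  structure(list(n_nodes = n_nodes, n_timepoints = n_timepoints, tr = tr,
                 n_motor = n_motor, n_control = n_control,
                 module_partition = as.integer(module_partition),
                 ar_coefficient = ar_coefficient, noise_sd = noise_sd,
                 target_nodes = target_nodes,
                 effect_strength = effect_strength,
                 behavior_coupling = behavior_coupling,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# stationary AR(1) series, marginal sd 1
ar1_series <- function(n, phi) {
  innov <- stats::rnorm(n, sd = sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = stats::rnorm(1)))
}

#' Synthetic node-coordinate table
#'
#' Builds an exactly x-mirror-symmetric node table from jittered anatomical
#' region coordinates: base coordinates are drawn from the packaged region
#' table, each contributing a (point, x-mirrored twin) pair, so hemisphere
#' flipping and nearest-region attribution are both exercisable and every
#' node has an exact mirror partner.  If `n_nodes` exceeds twice the
#' coordinate pool, the remainder is filled with a symmetric lattice.
#'
#' @param n_nodes number of nodes (even counts give perfect mirror pairing).
#' @param seed RNG seed for coordinate sampling and jitter.
#' @param jitter half-width in mm of the uniform jitter (default 2).
#' @return node table (`node_id, x, y, z`); node `2k-1` and `2k` are mirror
#'   partners.
#' @export
synthetic_node_table <- function(n_nodes, seed = 1, jitter = 2) {
  regions <- load_region_table()
  regions <- regions[is.finite(regions$x), ]
  with_seed(seed, {
    n_pairs <- ceiling(n_nodes / 2)
    pool <- nrow(regions)
    idx <- if (n_pairs <= pool) sample.int(pool, n_pairs)
    else c(rep(seq_len(pool), n_pairs %/% pool), sample.int(pool, n_pairs %% pool))
    base <- as.matrix(regions[idx, c("x", "y", "z")])
    base <- base + matrix(stats::runif(3 * n_pairs, -jitter, jitter),
                          ncol = 3)
    coords <- matrix(0, 2 * n_pairs, 3)
    coords[seq(1, 2 * n_pairs, by = 2), ] <- base
    mirror <- base; mirror[, 1] <- -mirror[, 1]
    coords[seq(2, 2 * n_pairs, by = 2), ] <- mirror
    coords <- coords[seq_len(n_nodes), , drop = FALSE]
    data.frame(node_id = paste0("n", seq_len(n_nodes)),
               x = round(coords[, 1], 2), y = round(coords[, 2], 2),
               z = round(coords[, 3], 2), stringsAsFactors = FALSE)
  })
}

#' Mirror-partner index of each node
#'
#' @param nodes node table whose coordinates are exactly x-mirror-symmetric.
#' @return integer vector: position of each node's `(-x, y, z)` twin (`NA`
#'   when absent).
#' @export
mirror_partners <- function(nodes) {
  key <- paste(nodes$x, nodes$y, nodes$z)
  mkey <- paste(-nodes$x, nodes$y, nodes$z)
  match(mkey, key)
}

# latent AR(1) draws for one session: K community factors, one global
# factor, N node-noise series
gen_latents <- function(cfg, K) {
  Tn <- cfg$n_timepoints; phi <- cfg$ar_coefficient
  list(Fm = vapply(seq_len(K), function(k) ar1_series(Tn, phi), numeric(Tn)),
       g = ar1_series(Tn, phi),
       E = vapply(seq_len(cfg$n_nodes), function(i) ar1_series(Tn, phi),
                  numeric(Tn)))
}

# mix a subject-common latent draw with a session-specific one; `rel` is the
# between-session reliability of the latent signal (marginals unchanged)
mix_latents <- function(common, own, rel) {
  a <- sqrt(rel); b <- sqrt(1 - rel)
  list(Fm = a * common$Fm + b * own$Fm, g = a * common$g + b * own$g,
       E = a * common$E + b * own$E)
}

# one session's T x N series given latents, an N x K loading matrix and a
# per-node global-factor loading vector
gen_session <- function(cfg, latents, loadings, lam_global) {
  latents$Fm %*% t(loadings) + outer(latents$g, lam_global) +
    cfg$noise_sd * latents$E
}

# bridge-loading profile: total magnitude fixed, exponential decay of rank
# with decay length delta -- delta controls how many communities the bridge
# reaches, which is what moves betweenness in a binary thresholded graph
bridge_profile <- function(n_other, delta, total = 1.2) {
  w <- exp(-(seq_len(n_other) - 1) / max(delta, 0.05))
  total * w / sqrt(sum(w^2))
}

#' Cohort-level spatial template
#'
#' Draws the spatial structure shared by every subject of a cohort: per-node
#' community loadings (`U(0.6, 1.4)`), per-node global-factor loadings
#' (`U(0.1, 0.5)`), and one community bridging order per target node.
#' Sharing one template across subjects makes them differ only in their
#' hub-shift magnitude and in realisation noise, not in spatial structure.
#' When a mirror-partner map is supplied the loadings are made exactly
#' x-mirror-symmetric, so left-lesion subjects have the same aligned
#' covariance structure as right-lesion subjects after lesion normalisation.
#'
#' @param config a [simulation_config()].
#' @param n_targets number of target nodes needing bridge orders.
#' @param twins optional mirror-partner index vector (see
#'   [mirror_partners()]).
#' @param template_seed seed for the template stream (default
#'   `config$seed + 104729`).
#' @return list with `lam_own`, `lam_global`, `bridge_order`.
#' @export
spatial_template <- function(config, n_targets = 0, twins = NULL,
                             template_seed = config$seed + 104729L) {
  K <- max(config$module_partition)
  n <- config$n_nodes
  with_seed(template_seed, {
    lam_own <- stats::runif(n, 0.6, 1.4)
    lam_global <- stats::runif(n, 0.1, 0.5)
    if (!is.null(twins) && !anyNA(twins)) {
      first <- seq_len(n) < twins                    # first member of each pair
      lam_own[!first] <- lam_own[twins[!first]]
      lam_global[!first] <- lam_global[twins[!first]]
    }
    bridge_order <- replicate(max(1, n_targets), sample(seq_len(K)),
                              simplify = FALSE)
    list(lam_own = lam_own, lam_global = lam_global,
         bridge_order = bridge_order)
  })
}


#' Simulate one subject
#'
#' Session 1 draws node series from the block latent-factor model (one unit
#' loading on the node's own community factor, a weak global factor, AR(1)
#' noise).  Session 2 re-draws all factors and noise; target nodes
#' additionally load, with subject-specific magnitude `delta_s`, on every
#' *other* community factor, turning them into inter-community bridges (the
#' kind of change betweenness centrality rewards).  For the motor group the
#' hub shift and the simulated UE-FM recovery are drawn jointly:
#' `delta_s = effect_strength * (coupling * dUEFM_norm + (1 - coupling) * u)`
#' with `u ~ U(0,1)`, so coupling 1 ties them deterministically and
#' coupling 0 decouples them.
#'
#' @param config a [simulation_config()].
#' @param group `"motor"` or `"control"`.
#' @param subject_seed integer seed for this subject's stream.
#' @param subject_id identifier (default derived from the seed).
#' @param target_nodes node indices of the hub shift for this subject
#'   (defaults to `config$target_nodes`; may be pre-mirrored by the caller
#'   for left-lesion subjects).
#' @param spatial optional cohort-level spatial template from
#'   [spatial_template()]; when `NULL` the subject draws its own loadings and
#'   bridge orders (standalone use).  [simulate_cohort()] passes one shared
#'   template so that subjects differ only in their shift magnitude and in
#'   factor/noise realisations, not in spatial structure.
#' @return list with `session1`, `session2` (T x N matrices, columns named by
#'   node index), `clinical` (one-row data.frame), `truth` (one-row
#'   data.frame with `delta_s` and `delta_uefm`).
#' @export
simulate_subject <- function(config, group = c("motor", "control"),
                             subject_seed, subject_id = NULL,
                             target_nodes = config$target_nodes,
                             spatial = NULL) {
  stopifnot(inherits(config, "sim_config"))
  group <- match.arg(group)
  if (is.null(subject_id)) subject_id <- paste0("sub", subject_seed)
  if (!is.null(target_nodes)) {
    target_nodes <- as.integer(target_nodes)
    if (any(is.na(target_nodes) | target_nodes < 1 |
            target_nodes > config$n_nodes)) {
      stop("target_nodes outside 1..n_nodes", call. = FALSE)
    }
  }
  with_seed(subject_seed, {
    lesion_side <- sample(c("Left", "Right"), 1)
    if (group == "motor") {
      rankin_t1 <- sample(1:2, 1, prob = c(1, 2))
      barthel_t1 <- sample(c(85, 90, 95), 1)
      nihss <- sample(0:8, 1)
      uefm_t1 <- round(stats::runif(1, 50, 66))
      rho <- stats::runif(1)                       # latent recovery fraction
      duefm <- round(rho * (66 - uefm_t1))
      uefm_t2 <- uefm_t1 + duefm
      lefm_t1 <- round(stats::runif(1, 30, 34))
      lefm_t2 <- min(34, lefm_t1 + round(rho * (34 - lefm_t1)))
      rankin_t2 <- max(0, rankin_t1 - as.integer(rho > 0.5))
      barthel_t2 <- min(100, barthel_t1 + 5 * round(2 * rho))
      duefm_norm <- duefm / 16                     # max headroom of the U[50,66] baseline
      u <- stats::runif(1)
      delta_s <- config$effect_strength *
        (config$behavior_coupling * duefm_norm +
           (1 - config$behavior_coupling) * u)
    } else {
      rankin_t1 <- sample(0:1, 1, prob = c(4, 3))
      barthel_t1 <- 100
      nihss <- sample(0:2, 1)
      uefm_t1 <- uefm_t2 <- lefm_t1 <- lefm_t2 <- NA_real_
      duefm <- NA_real_
      rankin_t2 <- max(0, rankin_t1 - sample(0:1, 1))
      barthel_t2 <- 100
      delta_s <- config$effect_strength * stats::runif(1)
    }
    censored <- stats::rpois(2, 4)                 # scrubbing counts, both sessions

    # Spatial structure (loadings and bridge orders) is fixed across the
    # subject's two sessions, so between-session differences at non-target
    # nodes are pure estimation noise; heterogeneous loadings spread the
    # correlation values so threshold crossings respond gradually rather
    # than community-at-a-time.
    K <- max(config$module_partition)
    if (is.null(spatial)) {
      spatial <- spatial_template(config, n_targets = length(target_nodes))
    }
    comm <- config$module_partition
    L1 <- matrix(0, config$n_nodes, K)
    L1[cbind(seq_len(config$n_nodes), comm)] <- spatial$lam_own
    L2 <- L1
    # Target nodes bridge the other communities with a fixed total loading
    # whose exponential reach grows with the shift: in a binary thresholded
    # graph betweenness responds to how many communities a node bridges, not
    # to how strong an already supra-threshold correlation is, so a scaled
    # fixed profile saturates immediately.  Baseline reach > 0 keeps BC1
    # away from zero, since the relative change (BC2-BC1)/BC1 is pure
    # denominator noise at BC1 ~ 0.
    base_reach <- 0.7
    if (length(target_nodes)) {
      for (t in seq_along(target_nodes)) {
        i <- target_nodes[t]
        perm <- spatial$bridge_order[[t]]
        others <- perm[perm != comm[i]]
        L1[i, others] <- bridge_profile(length(others), base_reach)
        L2[i, others] <- bridge_profile(length(others), base_reach + delta_s)
      }
    }
    # Sessions share part of their latent realisation (between-session
    # reliability of resting-state connectivity estimates is well above
    # zero); the shared component cancels in the session difference, as it
    # does in repeated scans of the same brain.  The session pair remains
    # exchangeable: the two sessions play symmetric roles in the mixture.
    session_reliability <- 0.98
    common <- gen_latents(config, K)
    l1 <- mix_latents(common, gen_latents(config, K), session_reliability)
    l2 <- mix_latents(common, gen_latents(config, K), session_reliability)
    s1 <- gen_session(config, l1, L1, spatial$lam_global)
    s2 <- gen_session(config, l2, L2, spatial$lam_global)
    colnames(s1) <- colnames(s2) <- paste0("n", seq_len(config$n_nodes))

    clinical <- data.frame(
      subject_id = subject_id, group = group, lesion_side = lesion_side,
      rankin_t1 = rankin_t1, rankin_t2 = rankin_t2,
      barthel_t1 = barthel_t1, barthel_t2 = barthel_t2, nihss = nihss,
      uefm_t1 = uefm_t1, uefm_t2 = uefm_t2,
      lefm_t1 = lefm_t1, lefm_t2 = lefm_t2, stringsAsFactors = FALSE)
    truth <- data.frame(subject_id = subject_id, group = group,
                        lesion_side = lesion_side, delta_s = delta_s,
                        delta_uefm = duefm, stringsAsFactors = FALSE)
    list(session1 = s1, session2 = s2, clinical = clinical, truth = truth,
         censored_volumes = censored)
  })
}

#' Simulate a full two-session cohort
#'
#' Generates `n_motor + n_control` subjects with independent, reproducible
#' per-subject seeds derived from the master seed by a fixed offset.  When
#' `config$target_nodes` is `NULL`, the hub-shift targets default to the
#' contralesional (left-side) primary-sensorimotor nodes of the synthetic
#' node table; for left-lesion subjects the target set is x-mirrored so the
#' planted effect stays contralesional after downstream lesion
#' normalisation.
#'
#' @param config a [simulation_config()].
#' @param node_table optional node table; defaults to
#'   [synthetic_node_table()] under the master seed.
#' @return object of class `fc_cohort`: list with `series` (per subject:
#'   `session1`, `session2`), `clinical`, `ground_truth`, `scrub`,
#'   `node_table`, `target_nodes`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), node_table = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(node_table)) {
    node_table <- synthetic_node_table(config$n_nodes, seed = config$seed)
  }
  if (nrow(node_table) != config$n_nodes) {
    stop("node table size does not match n_nodes", call. = FALSE)
  }
  targets <- config$target_nodes
  if (is.null(targets)) {
    map <- assign_nodes_to_regions(node_table, load_region_table())
    rois <- suppressWarnings(roi_node_sets(map, default_roi_spec()))
    targets <- match(rois$SM1$Left, node_table$node_id)
    targets <- targets[!is.na(targets)]
  }
  twins <- mirror_partners(node_table)
  spatial <- spatial_template(config, n_targets = length(targets),
                              twins = twins)
  groups <- c(rep("motor", config$n_motor), rep("control", config$n_control))
  series <- list(); clin <- list(); truth <- list(); scrub <- list()
  for (i in seq_along(groups)) {
    sid <- sprintf("S%02d", i)
    sseed <- config$seed + 7919L * i
    subj <- simulate_subject(config, groups[i], sseed, subject_id = sid,
                             target_nodes = targets, spatial = spatial)
    # left-lesion subjects get the mirrored plant so that, once their node
    # table is flipped lesion-to-right, the shifted nodes sit contralesional
    if (subj$clinical$lesion_side == "Left" && length(targets)) {
      tw <- twins[targets]
      if (!anyNA(tw)) {
        subj <- simulate_subject(config, groups[i], sseed, subject_id = sid,
                                 target_nodes = tw, spatial = spatial)
      }
    }
    series[[sid]] <- list(session1 = subj$session1, session2 = subj$session2)
    clin[[sid]] <- subj$clinical
    truth[[sid]] <- subj$truth
    scrub[[sid]] <- data.frame(subject_id = sid, session = 1:2,
                               censored_volumes = subj$censored_volumes,
                               stringsAsFactors = FALSE)
  }
  structure(list(series = series,
                 clinical = do.call(rbind, c(clin, make.row.names = FALSE)),
                 ground_truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 scrub = do.call(rbind, c(scrub, make.row.names = FALSE)),
                 node_table = node_table, target_nodes = targets,
                 config = config),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf("<fc_cohort> %d subjects (%d motor, %d control), %d nodes, %d time points x 2 sessions\n",
              length(x$series), x$config$n_motor, x$config$n_control,
              x$config$n_nodes, x$config$n_timepoints))
  invisible(x)
}

#' Canonical toy graphs
#'
#' Small named graph families used as exact fixtures for the metric
#' definitions.
#'
#' @param name one of `"complete"`, `"star"`, `"path"`, `"ring"`, `"empty"`.
#' @param n node count (`star` needs n >= 2, `ring` n >= 3).
#' @return binary adjacency matrix.
#' @export
make_toy_graph <- function(name = c("complete", "star", "path", "ring", "empty"),
                           n) {
  name <- match.arg(name)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  A <- matrix(0, n, n)
  switch(name,
    complete = { A[] <- 1; diag(A) <- 0 },
    star = {
      if (n < 2) stop("star needs n >= 2", call. = FALSE)
      A[1, 2:n] <- 1; A[2:n, 1] <- 1
    },
    path = {
      if (n >= 2) for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
    },
    ring = {
      if (n < 3) stop("ring needs n >= 3", call. = FALSE)
      for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
      A[1, n] <- A[n, 1] <- 1
    },
    empty = { }
  )
  A
}

#' Write a cohort to disk in plain-text formats
#'
#' One tab-separated file per subject-session (T rows x N columns, header row
#' of node ids), plus `clinical.csv`, `nodes.csv`, `scrub.csv` and
#' `ground_truth.csv`.
#'
#' @param cohort an `fc_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (sid in names(cohort$series)) {
    for (ses in 1:2) {
      p <- file.path(dir, sprintf("%s_ses-%d_timeseries.tsv", sid, ses))
      utils::write.table(
        round(cohort$series[[sid]][[paste0("session", ses)]], 6),
        p, sep = "\t", row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
  }
  for (tbl in c("clinical", "scrub", "ground_truth")) {
    p <- file.path(dir, paste0(tbl, ".csv"))
    utils::write.csv(cohort[[tbl]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "nodes.csv")
  utils::write.csv(cohort$node_table, p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
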