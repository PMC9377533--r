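# small dimensions keep the simulation tests fast; the full-size study
# geometry is exercised once at the end
small_cfg <- function(seed = 5, ...) {
  simulation_config(n_nodes = 16, n_timepoints = 20, n_motor = 2,
                    n_control = 2, seed = seed, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_nodes = 2), "n_nodes")
  expect_error(simulation_config(n_timepoints = 5), "n_timepoints")
  expect_error(simulation_config(n_motor = 0, n_control = 1), ">= 2")
  expect_error(simulation_config(ar_coefficient = 1), "ar_coefficient")
  expect_error(simulation_config(effect_strength = -1), "effect_strength")
  expect_error(simulation_config(behavior_coupling = 1.5), "behavior_coupling")
  expect_error(simulation_config(n_nodes = 16, target_nodes = 17), "target_nodes")
  expect_error(simulate_subject(small_cfg(), "motor", 1, target_nodes = 99),
               "target_nodes")
})

test_that("identical config and seed give bit-identical cohorts", {
  c1 <- simulate_cohort(small_cfg())
  c2 <- simulate_cohort(small_cfg())
  expect_identical(c1$series, c2$series)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$ground_truth, c2$ground_truth)

  c3 <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(c1$series$S01$session1, c3$series$S01$session1))
})

test_that("cohort structure matches the configuration", {
  coh <- simulate_cohort(small_cfg())
  expect_length(coh$series, 4)
  for (s in coh$series) {
    expect_equal(dim(s$session1), c(20, 16))
    expect_equal(dim(s$session2), c(20, 16))
  }
  expect_equal(sum(coh$clinical$group == "motor"), 2)
  expect_equal(sum(coh$clinical$group == "control"), 2)

  # generated scores re-classify to the generating group
  expect_equal(assign_group(coh$clinical$rankin_t1, coh$clinical$barthel_t1),
               coh$clinical$group)

  # score ranges respect the clinical scales
  motor <- coh$clinical[coh$clinical$group == "motor", ]
  expect_true(all(motor$uefm_t1 >= 0 & motor$uefm_t2 <= 66))
  expect_true(all(motor$uefm_t2 >= motor$uefm_t1))
  expect_true(all(coh$ground_truth$delta_uefm[!is.na(coh$ground_truth$delta_uefm)] >= 0))
  control <- coh$clinical[coh$clinical$group == "control", ]
  expect_true(all(is.na(control$uefm_t1)))
  expect_true(all(control$barthel_t1 == 100))
  expect_true(all(control$rankin_t1 %in% 0:1))
})

test_that("a control-only cohort has no populated UE-FM column", {
  coh <- simulate_cohort(simulation_config(n_nodes = 16, n_timepoints = 20,
                                           n_motor = 0, n_control = 2, seed = 7))
  expect_length(coh$series, 2)
  expect_true(all(is.na(coh$clinical$uefm_t1)))
})

test_that("a null effect leaves the two sessions exchangeable at targets", {
  # with effect_strength = 0 the loadings are identical across sessions, so
  # P(BC2 > BC1) should be ~ 1/2 at the would-be target nodes
  cfg <- simulation_config(n_nodes = 24, n_timepoints = 60, n_motor = 2,
                           n_control = 0, effect_strength = 0,
                           noise_sd = 0.5, seed = 11,
                           target_nodes = c(1, 5, 9, 13))
  wins <- c()
  for (rep in 1:8) {
    cfg$seed <- 11L + rep
    coh <- simulate_cohort(cfg)
    expect_true(all(coh$ground_truth$delta_s == 0))
    for (s in coh$series) {
      a1 <- proportional_threshold(pearson_matrix(s$session1), 0.2)
      a2 <- proportional_threshold(pearson_matrix(s$session2), 0.2)
      b1 <- betweenness(shortest_paths(a1))$values[cfg$target_nodes]
      b2 <- betweenness(shortest_paths(a2))$values[cfg$target_nodes]
      keep <- b1 != b2
      wins <- c(wins, (b2 > b1)[keep])
    }
  }
  expect_gt(mean(wins), 0.3)
  expect_lt(mean(wins), 0.7)
})

test_that("behavior_coupling = 0 decouples the hub shift from recovery", {
  cfg <- simulation_config(n_nodes = 16, n_timepoints = 20, n_motor = 2,
                           n_control = 0, behavior_coupling = 0, seed = 13)
  truths <- do.call(rbind, lapply(1:40, function(i) {
    simulate_subject(cfg, "motor", 1000 + 17 * i)$truth
  }))
  expect_lt(abs(cor(truths$delta_s, truths$delta_uefm)), 0.4)
})

test_that("a strong planted shift raises betweenness at target nodes", {
  # supplementary (expectation-over-replicates) version of plant recovery:
  # pooled medians separate cleanly even where pooled means are destabilised
  # by relative-change outliers at near-zero baselines
  dt <- c(); dn <- c()
  for (rep in 1:3) {
    cfg <- simulation_config(n_nodes = 64, n_timepoints = 120, n_motor = 4,
                             n_control = 0, effect_strength = 2.5,
                             behavior_coupling = 1, noise_sd = 0.5,
                             seed = 400 + rep)
    coh <- simulate_cohort(cfg)
    tn <- coh$target_nodes
    expect_gt(length(tn), 0)
    for (s in coh$series) {
      a1 <- proportional_threshold(pearson_matrix(s$session1), 0.2)
      a2 <- proportional_threshold(pearson_matrix(s$session2), 0.2)
      d <- delta_metric(betweenness(shortest_paths(a1)),
                        betweenness(shortest_paths(a2)))
      dt <- c(dt, d$delta[tn][d$defined[tn]])
      dn <- c(dn, d$delta[-tn][d$defined[-tn]])
    }
  }
  expect_gt(median(dt), median(dn))
  expect_gt(mean(dt), 0)
})

test_that("the default configuration reproduces the study geometry", {
  cfg <- simulation_config()
  expect_equal(cfg$n_nodes, 264)
  expect_equal(cfg$n_timepoints, 180)
  expect_equal(cfg$n_motor + cfg$n_control, 13)
  coh <- simulate_cohort(cfg)
  expect_length(coh$series, 13)
  expect_equal(dim(coh$series$S01$session1), c(180, 264))
  expect_equal(nrow(coh$clinical), 13)
})
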