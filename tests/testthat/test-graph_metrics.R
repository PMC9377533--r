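test_that("closed-form families give exact metric values", {
  # complete graph K4: everyone adjacent
  k4 <- all_metrics(make_toy_graph("complete", 4))
  expect_equal(k4$D$values, rep(3, 4))
  expect_equal(k4$CC$values, rep(1, 4))
  expect_equal(k4$CPL$values, rep(1, 4))
  expect_equal(k4$BC$values, rep(0, 4))

  # star S5: centre bridges every leaf pair
  s5 <- all_metrics(make_toy_graph("star", 5))
  expect_equal(s5$D$values, c(4, 1, 1, 1, 1))
  expect_equal(s5$CC$values, rep(0, 5))
  expect_equal(s5$BC$values[1], 1)
  expect_equal(s5$BC$values[-1], rep(0, 4))
  expect_equal(s5$CPL$values[1], 1)

  # path P3: middle node is the sole bridge
  p3 <- all_metrics(make_toy_graph("path", 3))
  expect_equal(p3$BC$values, c(0, 1, 0))
  expect_equal(p3$CPL$values, c(1.5, 1, 1.5))

  # ring C5: vertex-transitive, so every metric vector is constant
  c5 <- all_metrics(make_toy_graph("ring", 5))
  expect_equal(c5$D$values, rep(2, 5))
  expect_equal(c5$CC$values, rep(0, 5))
  expect_equal(c5$CPL$values, rep(1.5, 5))
  expect_true(all(abs(c5$BC$values - c5$BC$values[1]) < 1e-12))

  # empty graph
  e3 <- degree(make_toy_graph("empty", 3))
  expect_equal(e3$values, rep(0, 3))
})

test_that("shortest-path counts match hand-derived cases", {
  p3 <- shortest_paths(make_toy_graph("path", 3))
  expect_equal(p3$lengths[1, 3], 2)
  expect_equal(p3$counts[1, 3], 1)
  expect_equal(path_through_counts(p3, 2)[1, 3], 1)

  c4 <- shortest_paths(make_toy_graph("ring", 4))
  expect_equal(c4$lengths[1, 3], 2)
  expect_equal(c4$counts[1, 3], 2)  # two equal routes around the square

  # disconnected pair: infinite length, zero count
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  spd <- shortest_paths(A)
  expect_equal(spd$lengths[1, 3], Inf)
  expect_equal(spd$counts[1, 3], 0)
})

test_that("characteristic path length policies handle disconnection", {
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  spd <- shortest_paths(A)
  lit <- char_path_length(spd, "literal")
  expect_true(all(!is.finite(lit$values)))
  reach <- char_path_length(spd, "reachable")
  expect_equal(reach$values, rep(1, 4))
  expect_equal(attr(reach, "unreachable"), rep(2, 4))

  # isolated node is NaN under the reachable policy
  B <- make_toy_graph("path", 3)
  B2 <- rbind(cbind(B, 0), 0)
  r2 <- char_path_length(shortest_paths(B2), "reachable")
  expect_true(is.nan(r2$values[4]))
})

test_that("all four metrics equal the brute-force oracles on random graphs", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    A <- random_adjacency(n, stats::runif(1, 0.15, 0.85))
    m <- all_metrics(A)
    spd <- oracle_spd(A)
    expect_identical(m$D$values, oracle_degree(A))
    expect_equal(m$CC$values, oracle_clustering(A), tolerance = 1e-12)
    expect_equal(m$CPL$values, oracle_cpl(spd), tolerance = 1e-12)
    expect_equal(m$BC$values, oracle_bc(spd), tolerance = 1e-12)
    # implementation's sigma counts against enumeration
    impl <- shortest_paths(A)
    expect_equal(impl$lengths, spd$d)
    expect_equal(impl$counts, spd$sigma)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 8
    A <- random_adjacency(n, 0.4)
    perm <- sample(n)
    Ap <- A[perm, perm]
    m <- all_metrics(A); mp <- all_metrics(Ap)
    for (metric in names(m)) {
      expect_equal(mp[[metric]]$values, m[[metric]]$values[perm],
                   tolerance = 1e-12)
    }
  }
})

test_that("normalisation bounds hold on random graphs", {
  set.seed(11)
  for (rep in 1:20) {
    A <- random_adjacency(sample(3:12, 1), stats::runif(1, 0.1, 0.9))
    m <- all_metrics(A)
    expect_true(all(m$CC$values >= 0 & m$CC$values <= 1))
    expect_true(all(m$BC$values >= 0 & m$BC$values <= 1))
    expect_true(all(m$D$values == floor(m$D$values)))
  }
})

test_that("degenerate and invalid adjacencies are rejected", {
  expect_warning(bc2 <- betweenness(shortest_paths(make_toy_graph("path", 2))),
                 "fewer than 3")
  expect_equal(bc2$values, c(0, 0))
  expect_error(as_adjacency(matrix(c(0, 2, 2, 0), 2)), "0 or 1")
  expect_error(as_adjacency(matrix(c(1, 0, 0, 0), 2)), "diagonal")
  expect_error(as_adjacency(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("toy graph families are constructed correctly", {
  expect_equal(sum(make_toy_graph("complete", 4)) / 2, 6)
  st <- make_toy_graph("star", 5)
  expect_equal(rowSums(st), c(4, 1, 1, 1, 1))
  expect_equal(sum(make_toy_graph("empty", 3)), 0)
  expect_error(make_toy_graph("ring", 2), "ring")
  expect_error(make_toy_graph("petersen", 10))
})
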