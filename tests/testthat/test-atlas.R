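test_that("node tables load, with parse errors naming the offender", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("node_id,x,y,z", "n1,1,2,3", "n2,-4,5,6"), tmp)
  nt <- load_node_table(tmp)
  expect_equal(nrow(nt), 2)
  expect_equal(nt$x, c(1, -4))

  writeLines(c("node_id\tx\ty\tz", "n1\t1\t2\t3"), tmp)
  expect_equal(nrow(load_node_table(tmp)), 1)   # TSV autodetected

  writeLines(character(), tmp)
  expect_error(load_node_table(tmp), "empty")

  writeLines(c("node_id,x,y,z", "n1,1,2,3", "n1,4,5,6"), tmp)
  expect_error(load_node_table(tmp), "n1")

  writeLines(c("node_id,x,y,z", "n1,foo,2,3"), tmp)
  expect_error(load_node_table(tmp), "row\\(s\\): 1")
})

test_that("packaged region table matches its documented shape", {
  rt <- load_region_table()
  expect_true(all(c("region", "abbreviation", "side", "x", "y", "z") %in%
                    names(rt)))
  expect_true(all(rt$side %in% c("Left", "Right")))
  # dash entries carry empty coordinate lists
  expect_true(any(!is.finite(rt$x)))
  expect_true(sum(is.finite(rt$x)) > 100)
})

test_that("lesion flipping negates x for left lesions and is an involution", {
  nt <- data.frame(node_id = c("a", "b"), x = c(23, -40), y = c(10, 2),
                   z = c(1, -5))
  expect_equal(flip_lesion_to_right(nt, "Right"), nt)
  fl <- flip_lesion_to_right(nt, "Left")
  expect_equal(fl$x, c(-23, 40))
  expect_equal(fl$y, nt$y)
  expect_equal(fl$z, nt$z)
  expect_error(flip_lesion_to_right(nt, "left"), "Left")

  set.seed(9)
  for (rep in 1:10) {
    nt2 <- data.frame(node_id = paste0("n", 1:20),
                      x = rnorm(20, sd = 40), y = rnorm(20, sd = 40),
                      z = rnorm(20, sd = 30))
    expect_equal(flip_lesion_to_right(flip_lesion_to_right(nt2, "Left"),
                                      "Left"), nt2)
  }
})

test_that("region attribution hits exact table coordinates at distance zero", {
  rt <- load_region_table()
  nt <- data.frame(node_id = c("thL", "thR"),
                   x = c(-10, 9), y = c(-18, -4), z = c(7, 6))
  map <- assign_nodes_to_regions(nt, rt)
  expect_equal(map$region, c("Thalamus", "Thalamus"))
  expect_equal(map$side, c("Left", "Right"))
  expect_equal(map$distance, c(0, 0))
})

test_that("region attribution equals the brute-force nearest-neighbour scan", {
  rt <- load_region_table()
  coords <- rt[is.finite(rt$x), ]
  set.seed(10)
  nt <- data.frame(node_id = paste0("n", 1:50),
                   x = runif(50, -60, 60), y = runif(50, -90, 60),
                   z = runif(50, -40, 70))
  map <- assign_nodes_to_regions(nt, rt, max_distance = 15)
  for (i in seq_len(nrow(nt))) {
    dd <- sqrt((coords$x - nt$x[i])^2 + (coords$y - nt$y[i])^2 +
                 (coords$z - nt$z[i])^2)
    best <- which.min(dd)       # first minimum = row-order tie rule
    expect_equal(map$distance[i], dd[best], tolerance = 1e-12)
    if (dd[best] <= 15) {
      expect_true(map$mapped[i])
      expect_equal(map$region[i], coords$region[best])
      expect_equal(map$side[i], coords$side[best])
    } else {
      expect_false(map$mapped[i])
      expect_true(is.na(map$region[i]))
    }
  }
  # every node is either mapped or flagged, never both states
  expect_equal(map$mapped, !is.na(map$region))
})

test_that("roi_node_sets unions abbreviations per side", {
  rt <- load_region_table()
  coords <- rt[is.finite(rt$x), ]
  nt <- data.frame(node_id = paste0("n", seq_len(nrow(coords))),
                   x = coords$x, y = coords$y, z = coords$z)
  map <- assign_nodes_to_regions(nt, rt)
  rois <- roi_node_sets(map, list(SM1 = c("PrCG", "PoCG")))
  expected_left <- map$node_id[map$abbreviation %in% c("PrCG", "PoCG") &
                                 map$side == "Left"]
  expect_setequal(rois$SM1$Left, expected_left)

  expect_equal(roi_node_sets(map, list()), list())
  w <- capture_warnings(empty <- roi_node_sets(map, list(X = "NOPE")))
  expect_length(w, 2)                       # one per side
  expect_match(w, "NOPE", all = TRUE)
  expect_length(empty$X$Left, 0)
})

test_that("hemisphere labels follow the sign of x", {
  nt <- data.frame(node_id = c("a", "b", "c"), x = c(-40, 44, 0),
                   y = 0, z = 0)
  expect_equal(node_hemisphere(nt), c("CL", "IL", "midline"))
})

test_that("synthetic node tables are mirror-symmetric and reproducible", {
  nt1 <- synthetic_node_table(64, seed = 3)
  nt2 <- synthetic_node_table(64, seed = 3)
  expect_identical(nt1, nt2)
  tw <- mirror_partners(nt1)
  expect_false(anyNA(tw))
  expect_equal(tw[tw], seq_len(64))   # pairing is an involution
  nt3 <- synthetic_node_table(64, seed = 4)
  expect_false(identical(nt1, nt3))
})
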