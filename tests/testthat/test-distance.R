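test_that("pairwise distance is one minus the overlap coefficient", {
  a <- profile_from_motifs("A", list(c("AAA", "ATA"),
                                     c("AAA", "ACG", "CTC"), "CGC"))
  b <- profile_from_motifs("B", list(c("AAA", "ATA"), "CGC", "TTT", "GGG"))
  # |a∩b| = 2, min(|a|,|b|) = 3
  expect_equal(cam_distance(a, b), 1 / 3, tolerance = 1e-12)
  expect_identical(cam_distance(a, b), cam_distance(b, a))
  expect_identical(cam_distance(a, a), 0)
  disjoint <- profile_from_motifs("C", list("CCC", "GGG,TAT"))
  expect_identical(cam_distance(a, disjoint), 1)
})

test_that("sub-threshold overlap is clamped to the maximum distance", {
  pool <- sprintf("m%03d", 1:296)
  a <- fake_profile("A", c(pool[1:4], pool[5:100]))       # 100 motifs
  b <- fake_profile("B", c(pool[1:4], pool[101:296]))     # 200 motifs, |∩| = 4
  expect_identical(cam_distance(a, b), 1)                 # s = 0.04 < 0.05
  expect_equal(cam_distance(a, b, min_overlap = 0), 1 - 0.04,
               tolerance = 1e-12)
  expect_error(cam_distance(a, fake_profile("B", character(0))),
               class = "camphy_invalid_profile")
  aa <- fake_profile("B", "m001")
  aa$mode <- "amino_acid"
  expect_error(cam_distance(a, aa), class = "camphy_mode_mismatch")
})

test_that("distance stays in [0,1], respects the clamp gap, and decreases in overlap", {
  set.seed(101)
  pool <- sprintf("k%03d", 1:60)
  for (i in 1:200) {
    a <- fake_profile("A", sample(pool, sample(1:30, 1)))
    b <- fake_profile("B", sample(pool, sample(1:30, 1)))
    d <- cam_distance(a, b)
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_true(d <= 1 - 0.05 + 1e-12 || d == 1)
  }
  # monotonicity at fixed set sizes on the un-clamped branch
  sizes <- c(20L, 25L)
  d_by_overlap <- vapply(2:20, function(k) {
    a <- fake_profile("A", pool[1:sizes[1]])
    b <- fake_profile("B", c(pool[1:k], pool[31:(30 + sizes[2] - k)]))
    cam_distance(a, b)
  }, numeric(1))
  expect_true(all(diff(d_by_overlap) < 0))
})

test_that("the distance matrix is symmetric, zero-diagonal, input-ordered", {
  ids <- profile_from_motifs("X", list("AAA"))
  m0 <- cam_distance_matrix(list(
    ids, profile_from_motifs("Y", list("AAA")),
    profile_from_motifs("Z", list("AAA"))))
  expect_identical(unname(m0[upper.tri(m0) | lower.tri(m0)]), rep(0, 6))

  dis <- cam_distance_matrix(list(
    profile_from_motifs("X", list("AAA")),
    profile_from_motifs("Y", list("CCC")),
    profile_from_motifs("Z", list("GGG"))))
  expect_identical(unname(dis[upper.tri(dis)]), rep(1, 3))

  # four constructed profiles against hand-computed values
  p <- list(
    profile_from_motifs("a", list("AAA", "CCC", "GGG")),
    profile_from_motifs("b", list("AAA", "CCC", "TTT")),
    profile_from_motifs("c", list("AAA", "ACC", "ACG", "ACT")),
    profile_from_motifs("d", list("GGG", "TTT"))
  )
  m <- cam_distance_matrix(p)
  expect_identical(rownames(m), c("a", "b", "c", "d"))
  expect_equal(m["a", "b"], 1 - 2 / 3, tolerance = 1e-12)
  expect_equal(m["a", "c"], 1 - 1 / 3, tolerance = 1e-12)
  expect_equal(m["a", "d"], 1 - 1 / 2, tolerance = 1e-12)
  expect_equal(m["b", "d"], 1 - 1 / 2, tolerance = 1e-12)
  expect_equal(m["c", "d"], 1, tolerance = 0)
  expect_identical(unclass(m), t(unclass(m)))

  expect_error(cam_distance_matrix(p[1:2]), class = "camphy_usage")
  expect_error(cam_distance_matrix(c(p, p[2])),
               class = "camphy_duplicate_labels")
})

test_that("native and PHYLIP serialization round-trip at 6 decimals", {
  p <- list(
    profile_from_motifs("alpha", list("AAA", "CCC", "GGG")),
    profile_from_motifs("beta", list("AAA", "CCC", "TTT")),
    profile_from_motifs("gamma", list("AAA", "ACC", "ACG"))
  )
  m <- cam_distance_matrix(p)

  native <- tempfile()
  write_cam_matrix(m, native, "native")
  lines <- readLines(native)
  expect_length(lines, 4L)
  expect_match(lines[2], "0\\.333333")
  back <- read_cam_matrix(native, "native")
  expect_identical(rownames(back), rownames(m))
  expect_equal(unclass(back), unclass(m), tolerance = 1e-6,
               ignore_attr = TRUE)

  phy <- tempfile()
  write_cam_matrix(m, phy, "phylip")
  expect_identical(readLines(phy)[1], "3")
  back2 <- read_cam_matrix(phy, "phylip")
  expect_equal(unclass(back2), unclass(m), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("matrix parsing rejects malformed input with line numbers", {
  expect_error(read_cam_matrix(c("4", "a 0.0 0.1", "b 0.1 0.0"), "phylip"),
               class = "camphy_parse_error")
  lower <- c("3", "a", "b 0.200000", "c 0.300000 0.400000")
  expect_error(read_cam_matrix(lower, "phylip"), "lower-triangle")
  bad <- c("species\ta\tb", "a\t0\tx", "b\tx\t0")
  expect_error(read_cam_matrix(bad, "native"), "non-numeric")
  asym <- c("3", "a 0.0 0.5 0.1", "b 0.1 0.0 0.1", "c 0.1 0.1 0.0")
  expect_error(read_cam_matrix(asym, "phylip"), "asymmetric")

  big <- cam_distance_matrix(list(
    profile_from_motifs("longnamecollision1", list("AAA")),
    profile_from_motifs("longnamecollision2", list("CCC")),
    profile_from_motifs("zeta", list("GGG"))))
  expect_error(write_cam_matrix(big, tempfile(), "phylip"),
               class = "camphy_phylip_collision")
})

test_that("PHYLIP output is readable by an independent parser", {
  skip_if_not_installed("phangorn")
  p <- list(
    profile_from_motifs("alpha", list("AAA", "CCC", "GGG")),
    profile_from_motifs("beta", list("AAA", "CCC", "TTT")),
    profile_from_motifs("gamma", list("AAA", "ACC", "ACG"))
  )
  m <- cam_distance_matrix(p)
  phy <- tempfile()
  write_cam_matrix(m, phy, "phylip")
  oracle <- as.matrix(phangorn::readDist(phy))
  expect_equal(unclass(oracle[rownames(m), colnames(m)]), unclass(m),
               tolerance = 1e-6, ignore_attr = TRUE)
})
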