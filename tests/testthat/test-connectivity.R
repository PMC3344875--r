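test_that("fisher_z matches arctanh and caps perfect correlations", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)  # atanh oracle
  expect_equal(fisher_z(1), 3.8002, tolerance = 1e-4)    # atanh(0.999)
  expect_equal(fisher_z(-1), -fisher_z(1))
  expect_error(fisher_z(1.01), "outside")
})

test_that("local correlation maps match a direct Pearson + arctanh oracle", {
  # 2x2 grid of hand-written length-8 series
  s <- rbind(c(1, 2, 3, 4, 5, 6, 7, 8),
             c(2, 1, 4, 3, 6, 5, 8, 7),
             c(8, 7, 6, 5, 4, 3, 2, 1),
             c(1, -1, 1, -1, 1, -1, 1, -1))
  # flat pixel order is column-major, so row p of `s` is pixel p
  g <- ts_grid(array(s, c(2, 2, 8)), tr_seconds = 3)
  m <- local_correlation_map(g, c(1, 1))
  for (p in 1:4) {
    rc <- arrayInd(p, c(2, 2))
    r <- cor(s[1, ], s[p, ])
    expect_equal(m$values[rc[1], rc[2]],
                 atanh(pmin(pmax(r, -0.999), 0.999)), tolerance = 1e-12)
  }
  # seed's own value is the capped maximum z
  expect_equal(m$values[1, 1], atanh(0.999))
})

test_that("a grid of identical series gives the capped maximum everywhere", {
  x <- rnorm(16)
  g <- ts_grid(array(rep(x, each = 9), c(3, 3, 16)), tr_seconds = 3)
  m <- local_correlation_map(g, c(2, 2))
  expect_true(all(abs(m$values - atanh(0.999)) < 1e-12))
})

test_that("correlation maps are symmetric and affine-invariant", {
  set.seed(31)
  g <- ts_grid(array(rnorm(4 * 4 * 24), c(4, 4, 24)), tr_seconds = 3)
  ma <- local_correlation_map(g, c(1, 2))
  mb <- local_correlation_map(g, c(3, 4))
  expect_equal(ma$values[3, 4], mb$values[1, 2], tolerance = 1e-12)
  # rescale one pixel's series affinely: maps unchanged
  g2 <- g
  g2$data[2, 2, ] <- 5 * g2$data[2, 2, ] - 3
  m2 <- local_correlation_map(g2, c(1, 2))
  expect_equal(m2$values, ma$values, tolerance = 1e-9)
})

test_that("zero-variance pixels are reported by coordinate", {
  g <- ts_grid(array(rnorm(9 * 12), c(3, 3, 12)), tr_seconds = 3)
  g$data[2, 3, ] <- 7
  expect_error(local_correlation_map(g, c(1, 1)), "row 2, col 3")
})

test_that("target profiles match the Pearson oracle on orthogonal targets", {
  t_len <- 240; tr <- 3
  tt <- (seq_len(t_len) - 1) * tr
  targ <- rbind(sin(2 * pi * 0.02 * tt), sin(2 * pi * 0.04 * tt),
                sin(2 * pi * 0.06 * tt))
  g <- ts_grid(array(rep(targ[2, ], each = 4), c(2, 2, t_len)),
               tr_seconds = tr)
  pr <- target_correlation_profile(g, c(1, 1), target_set(targ))
  expect_equal(pr$z[2], atanh(0.999))
  expect_lt(max(abs(pr$z[c(1, 3)])), 0.05)
  # seed identical to a target caps at max z
  expect_error(target_set(targ[0, , drop = FALSE]), "non-empty")
})

test_that("eta2 follows the definition and stays in [0, 1]", {
  expect_identical(eta2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(eta2(c(0, 1), c(1, 0)), 0)   # hand evaluation: num=den=1
  expect_warning(v <- eta2(c(2, 2), c(2, 2)), "constant")
  expect_identical(v, 1)
  set.seed(32)
  for (i in 1:25) {
    a <- rnorm(5); b <- rnorm(5)
    e <- eta2(a, b)
    expect_equal(e, eta2_brute(a, b), tolerance = 1e-12)
    expect_gte(e, 0); expect_lte(e, 1)
  }
})

test_that("eta2 maps agree with pairwise eta2 and are symmetric", {
  set.seed(33)
  sim <- simulate_flatmap(height = 10, width = 10, t_len = 96, seed = 5)
  g <- sim$grid
  Z <- arealmap:::profile_matrix(g, sim$targets)
  m <- eta2_map(g, c(2, 3), sim$targets)
  idx <- which(g$mask)
  seedrow <- match((3 - 1) * 10 + 2, idx)
  for (p in c(1, 17, 55, 100)) {
    rc <- arrayInd(idx[p], c(10, 10))
    expect_equal(m$values[rc[1], rc[2]], eta2(Z[seedrow, ], Z[p, ]),
                 tolerance = 1e-12)
  }
  expect_equal(m$values[2, 3], 1)
  m2 <- eta2_map(g, c(7, 8), sim$targets)
  expect_equal(m$values[7, 8], m2$values[2, 3], tolerance = 1e-12)
})

test_that("eta2 separates areas: within-area similarity exceeds between-area", {
  sim <- simulate_flatmap(height = 12, width = 12, t_len = 256, seed = 7)
  m <- eta2_map(sim$grid, c(6, 3), sim$targets)    # seed in area 1
  same <- sim$truth$labels == sim$truth$labels[6, 3]
  expect_gt(mean(m$values[same]), mean(m$values[!same]))
})

test_that("local maps bridge to target profiles over the ROI's own pixels", {
  set.seed(34)
  g <- ts_grid(array(rnorm(3 * 3 * 32), c(3, 3, 32)), tr_seconds = 3)
  s <- arealmap:::grid_series(g)
  roi_targets <- target_set(matrix(s, nrow(s), ncol(s)))
  pr <- target_correlation_profile(g, c(2, 2), roi_targets)
  m <- local_correlation_map(g, c(2, 2))
  expect_equal(pr$z, m$values[which(g$mask)], tolerance = 1e-12)
})

test_that("contralateral discs follow the <= radius rule on the lattice", {
  set.seed(35)
  g <- ts_grid(array(rnorm(9 * 9 * 16), c(9, 9, 16)), tr_seconds = 3,
               pixel_mm = 2)
  # mirrored seed of (5, 5) on a 9-wide grid is (5, 5); 2 mm radius with
  # 2 mm pixels reaches exactly the 4-neighbors: 5 pixels in the disc
  ts1 <- contralateral_target_set(g, matrix(c(5, 5), 1), radius_mm = 2)
  expect_identical(nrow(ts1$series), 5L)
  expect_true(all(abs(ts1$coords[, 1] - 5) + abs(ts1$coords[, 2] - 5) <= 1))
  # two adjacent seeds: union without duplicates
  ts2 <- contralateral_target_set(g, rbind(c(5, 5), c(5, 6)), radius_mm = 2)
  expect_identical(nrow(ts2$series), 8L)    # 5 + 5 with 2 shared pixels
  expect_identical(anyDuplicated(ts2$coords), 0L)
  # union over every seed covers the full contralateral mask
  seeds <- which(g$mask, arr.ind = TRUE)
  ts3 <- contralateral_target_set(g, seeds, radius_mm = 2)
  expect_identical(nrow(ts3$series), sum(g$mask))
})
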