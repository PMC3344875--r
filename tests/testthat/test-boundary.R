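full_map <- function(v, kind = "fisher_z", pixel = 2) {
  scalar_map(v, matrix(TRUE, nrow(v), ncol(v)), kind = kind, pixel_mm = pixel)
}

test_that("mask-renormalized smoothing preserves constants and obeys the semigroup", {
  mask <- matrix(TRUE, 15, 15); mask[1, 1] <- FALSE
  m <- scalar_map(matrix(0.7, 15, 15), mask, kind = "fisher_z", pixel_mm = 2)
  sm <- gaussian_smooth(m, fwhm_mm = 6)
  expect_equal(sm$values[mask], rep(0.7, sum(mask)), tolerance = 1e-12)

  # sigma in pixels for FWHM 6 mm at 2 mm pixels: 6 / (2.3548 * 2)
  expect_equal(arealmap:::fwhm_to_sigma_px(6, 2), 1.2740, tolerance = 1e-3)

  set.seed(41)
  big <- full_map(matrix(rnorm(41 * 41), 41, 41))
  twice <- gaussian_smooth(gaussian_smooth(big, fwhm_mm = 6), fwhm_mm = 6)
  once <- gaussian_smooth(big, fwhm_mm = 6 * sqrt(2))
  interior <- 15:27
  expect_equal(twice$values[interior, interior],
               once$values[interior, interior], tolerance = 1e-6)
})

test_that("an isolated impulse smooths to the kernel itself", {
  v <- matrix(0, 21, 21); v[11, 11] <- 1
  sm <- gaussian_smooth(full_map(v), fwhm_mm = 6)
  k <- arealmap:::gauss_kernel_1d(arealmap:::fwhm_to_sigma_px(6, 2))
  expect_equal(sm$values[11, 11], max(k)^2, tolerance = 1e-12)
  # mass preserved up to the mask-border renormalization of the 5-sigma tail
  expect_equal(sum(sm$values), 1, tolerance = 1e-7)
})

test_that("gradients match analytic values on linear ramps", {
  co <- matrix(rep(1:9, each = 9), 9, 9)   # co[i, j] = j
  ro <- matrix(rep(1:9, times = 9), 9, 9)  # ro[i, j] = i
  g1 <- gradient_map(full_map(3 * co))
  expect_equal(g1$magnitude$values[2:8, 2:8],
               matrix(3, 7, 7), tolerance = 1e-12)
  expect_equal(g1$direction[2:8, 2:8], matrix(0, 7, 7), tolerance = 1e-12)
  g2 <- gradient_map(full_map(ro + 2 * co))
  expect_equal(g2$magnitude$values[2:8, 2:8],
               matrix(sqrt(5), 7, 7), tolerance = 1e-12)
  g3 <- gradient_map(full_map(matrix(4, 9, 9)))
  expect_true(all(g3$magnitude$values == 0))
})

test_that("a vertical step yields one single-pixel-wide edge line", {
  em <- canny_edges(step_map(25, 25, at = 13))
  expect_true(any(em$edges))
  per_row <- rowSums(em$edges)
  expect_true(all(per_row == 1))                       # 1 pixel wide
  cols <- apply(em$edges, 1, which)
  expect_identical(length(unique(cols)), 1L)           # straight line
  expect_identical(cc_count(em$edges), 1L)             # single component
  expect_true(abs(unique(cols) - 13) <= 1)             # at the step
})

test_that("flat maps produce no edges", {
  em <- canny_edges(full_map(matrix(2.5, 25, 25)))
  expect_false(any(em$edges))
})

test_that("two parallel steps 8 pixels apart give two disjoint edge lines", {
  v <- matrix(0, 25, 25)
  v[, 9:16] <- 1       # rises at col 9, falls at col 17
  em <- canny_edges(full_map(v))
  expect_identical(cc_count(em$edges), 2L)
  expect_true(all(rowSums(em$edges) == 2))
})

test_that("probabilistic boundary maps are means of binary edge maps", {
  set.seed(42)
  mask <- matrix(TRUE, 8, 8)
  ems <- lapply(1:64, function(i) {
    e <- matrix(runif(64) < 0.3, 8, 8)
    e[1, 1] <- i <= 32            # pixel marked in exactly half the maps
    arealmap:::edge_map(e, mask)
  })
  pbm <- probabilistic_boundary_map(ems)
  counts <- Reduce(`+`, lapply(ems, `[[`, "edges"))
  expect_equal(pbm$values, counts / 64, tolerance = 1e-15)
  # a pixel marked in exactly half the maps scores exactly 0.5
  expect_true(any(counts == 32))
  expect_true(all(pbm$values[counts == 32] == 0.5))
  # order invariance
  pbm2 <- probabilistic_boundary_map(ems[sample(64)])
  expect_identical(pbm2$values, pbm$values)
  # duplicating one map moves probabilities toward it
  dup <- probabilistic_boundary_map(c(ems, ems[1]))
  shift <- dup$values - pbm$values
  expect_true(all(shift[ems[[1]]$edges] >= 0))
  expect_true(all(shift[!ems[[1]]$edges] <= 0))
})

test_that("edge detection is mirror-equivariant on tie-free maps", {
  set.seed(43)
  noise <- full_map(matrix(rnorm(625), 25, 25))
  sm <- gaussian_smooth(noise, fwhm_mm = 4)   # smooth, generic, tie-free
  em <- canny_edges(sm)
  mirrored <- sm
  mirrored$values <- sm$values[, 25:1]
  em_m <- canny_edges(mirrored)
  expect_identical(em_m$edges, em$edges[, 25:1])
})

test_that("the full local-method pipeline mirrors with its input", {
  sim <- simulate_flatmap(height = 10, width = 10, t_len = 64, seed = 9)
  p <- run_new_method(sim$grid)
  gm <- sim$grid
  gm$data <- gm$data[, 10:1, , drop = FALSE]
  gm$mask <- gm$mask[, 10:1, drop = FALSE]
  pm <- run_new_method(gm)
  expect_identical(pm$values, p$values[, 10:1])
})

test_that("boundary probability concentrates on a planted border", {
  sim <- simulate_flatmap(height = 12, width = 12, t_len = 256, seed = 11)
  p2 <- run_new_method(sim$grid)
  ridge_mean <- mean(p2$values[sim$truth$true_boundary])
  off <- !sim$truth$true_boundary &
    !true_boundary_pixels(sim$truth$labels + 0L * sim$truth$labels)
  expect_gt(ridge_mean, 3 * mean(p2$values[!sim$truth$true_boundary]))

  # one-area grid: no boundary anywhere near that strength
  labels1 <- matrix(1L, 12, 12)
  net <- make_network_signals(1, 256, seed = 12)
  g1 <- make_grid(labels1, net, w = 0.5, noise_seed = 13)
  p1 <- run_new_method(g1)
  expect_lt(max(p1$values, na.rm = TRUE), ridge_mean)
})

test_that("standard method with the ROI's own pixels tracks the local method", {
  sim <- simulate_flatmap(height = 12, width = 12, t_len = 256, seed = 14)
  s <- arealmap:::grid_series(sim$grid)
  self_targets <- target_set(matrix(s, nrow(s), ncol(s)))
  ps <- run_standard_method(sim$grid, self_targets)
  pn <- run_new_method(sim$grid)
  ridge_col <- function(p) which.max(colSums(p$values))
  expect_lte(abs(ridge_col(ps) - ridge_col(pn)), 1)
})

test_that("degenerate pipeline inputs are rejected", {
  mask <- matrix(FALSE, 5, 5); mask[3, 3] <- TRUE
  g <- ts_grid(array(rnorm(25 * 16), c(5, 5, 16)), mask = mask,
               tr_seconds = 3)
  expect_error(run_new_method(g), "at least 2")
  expect_error(probabilistic_boundary_map(list()), "at least one")
  sim <- simulate_flatmap(height = 10, width = 10, t_len = 64, seed = 15)
  expect_error(run_standard_method(sim$grid, targets = NULL), "target_set")
})
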