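# ---- shared spatial helpers -------------------------------------------------

# neighbor value matrix: out[i, j] = M[i + dr, j + dc], `fill` outside the grid
nbval <- function(M, dr, dc, fill = NA_real_) {
  h <- nrow(M); w <- ncol(M)
  out <- matrix(fill, h, w)
  r0 <- max(1L, 1L - dr); r1 <- min(h, h - dr)
  c0 <- max(1L, 1L - dc); c1 <- min(w, w - dc)
  if (r0 <= r1 && c0 <= c1)
    out[r0:r1, c0:c1] <- M[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc)]
  out
}

gauss_kernel_1d <- function(sigma_px) {
  # truncate at 5 sigma: keeps the Gaussian semigroup property
  # (smooth(sigma) twice == smooth(sigma*sqrt(2))) accurate to ~1e-7
  r <- max(1L, as.integer(ceiling(5 * sigma_px)))
  k <- exp(-((-r):r)^2 / (2 * sigma_px^2))
  k / sum(k)
}

# separable convolution with zero fill outside the grid
conv_sep <- function(M, k) {
  r <- (length(k) - 1L) %/% 2L
  tmp <- matrix(0, nrow(M), ncol(M))
  for (o in -r:r) tmp <- tmp + k[o + r + 1L] * nbval(M, o, 0L, fill = 0)
  out <- matrix(0, nrow(M), ncol(M))
  for (o in -r:r) out <- out + k[o + r + 1L] * nbval(tmp, 0L, o, fill = 0)
  out
}

fwhm_to_sigma_px <- function(fwhm_mm, pixel_mm) {
  fwhm_mm / (2 * sqrt(2 * log(2))) / pixel_mm
}

# core smoothing on a plain matrix + mask (mask-renormalized)
smooth_core <- function(values, mask, sigma_px) {
  v0 <- values
  v0[!mask] <- 0
  num <- conv_sep(v0, gauss_kernel_1d(sigma_px))
  den <- conv_sep(mask * 1, gauss_kernel_1d(sigma_px))
  out <- matrix(NA_real_, nrow(values), ncol(values))
  out[mask] <- num[mask] / den[mask]
  out
}

#' Mask-renormalized Gaussian smoothing of a scalar map
#'
#' Convolves the map with an isotropic Gaussian of the given full width at
#' half maximum, `sigma = fwhm_mm / (2 sqrt(2 ln 2)) / pixel_mm` pixels.
#' Kernel weight that falls on off-mask pixels is redistributed to the
#' on-mask support (division by the smoothed mask indicator), so constants
#' are preserved up to the mask border. This is the noise-reduction step of
#' the Canny edge detector; the conventional smoothing width for these
#' boundary maps is FWHM = 6 mm.
#'
#' @param map a [scalar_map()].
#' @param fwhm_mm Gaussian full width at half maximum in millimetres.
#' @param pixel_mm pixel pitch; defaults to the map's own, else 2 mm.
#' @return A smoothed [scalar_map()] of the same kind.
#' @export
gaussian_smooth <- function(map, fwhm_mm = 6.0, pixel_mm = NULL) {
  stopifnot(inherits(map, "scalar_map"), fwhm_mm > 0)
  if (is.null(pixel_mm)) pixel_mm <- if (is.null(map$pixel_mm)) 2 else map$pixel_mm
  if (!any(map$mask)) stop("empty mask")
  out <- smooth_core(map$values, map$mask, fwhm_to_sigma_px(fwhm_mm, pixel_mm))
  map$values <- out
  # smoothing can nudge bounded kinds past the bound by rounding only
  if (map$kind %in% c("probability", "eta2"))
    map$values[map$mask] <- pmin(pmax(map$values[map$mask], 0), 1)
  map
}

gradient_core <- function(values, mask) {
  v <- values
  v[!mask] <- NA_real_
  grad_axis <- function(dr, dc) {
    p <- nbval(v, dr, dc)    # neighbor at +1 along the axis
    m <- nbval(v, -dr, -dc)  # neighbor at -1
    hp <- !is.na(p); hm <- !is.na(m)
    g <- matrix(0, nrow(v), ncol(v))
    both <- hp & hm
    g[both] <- (p[both] - m[both]) / 2
    ponly <- hp & !hm
    g[ponly] <- p[ponly] - v[ponly]
    monly <- hm & !hp
    g[monly] <- v[monly] - m[monly]
    g[!mask] <- NA_real_
    g
  }
  gy <- grad_axis(1L, 0L)   # d/d(row)
  gx <- grad_axis(0L, 1L)   # d/d(col)
  list(gx = gx, gy = gy,
       magnitude = sqrt(gx^2 + gy^2),
       direction = atan2(gy, gx))
}

#' Spatial gradient of a scalar map
#'
#' Central differences on interior mask pixels, one-sided differences where
#' one neighbor along an axis is off the mask, zero where both are. Returns
#' the gradient magnitude as a [scalar_map()] of kind `"gradient"` and the
#' gradient direction (`atan2(d/drow, d/dcol)`, radians) as a plain matrix.
#'
#' @param map a [scalar_map()], normally smoothed first.
#' @return list with elements `magnitude` ([scalar_map()]) and `direction`
#'   (matrix).
#' @export
gradient_map <- function(map) {
  stopifnot(inherits(map, "scalar_map"))
  if (!any(map$mask)) stop("empty mask")
  g <- gradient_core(map$values, map$mask)
  list(magnitude = scalar_map(g$magnitude, map$mask, kind = "gradient",
                              pixel_mm = map$pixel_mm),
       direction = g$direction)
}

# offsets of the 4 quantized gradient sectors (row, col)
nms_sectors <- matrix(c(0L, 1L,   # ~0: horizontal gradient
                        1L, 1L,   # ~45 degrees
                        1L, 0L,   # ~90: vertical gradient
                        1L, -1L), # ~135 degrees
                      ncol = 2L, byrow = TRUE)

# Canny on a plain value matrix; returns logical edge matrix.
# Non-maximum suppression quantizes the gradient direction to 4 sectors and
# keeps a pixel iff its magnitude is >= the neighbor at the negative sector
# offset and strictly > the neighbor at the positive offset; the asymmetric
# tie-break thins 2-wide plateaus (e.g. an ideal step between two pixel
# columns) to a single line while keeping wider plateau ridges as the last
# pixel of the run. Hysteresis thresholds are quantiles of the nonzero
# gradient magnitudes on the mask; weak edge pixels survive iff 8-connected
# to a strong pixel through weak ones.
canny_core <- function(values, mask, sigma_px, low_q, high_q) {
  sm <- smooth_core(values, mask, sigma_px)
  g <- gradient_core(sm, mask)
  mag <- g$magnitude
  mag[!mask] <- NA_real_
  edges <- matrix(FALSE, nrow(values), ncol(values))
  mag_max <- max(mag[mask], 0, na.rm = TRUE)
  vscale <- max(abs(sm[mask]), na.rm = TRUE)
  # a flat map's numerical gradient residue (~1e-16 of the value scale)
  # must not seed edges
  if (!is.finite(mag_max) || mag_max <= 1e-10 * max(vscale, 1e-300))
    return(edges)
  # comparisons within gtol count as ties so that exactly symmetric inputs
  # (e.g. an ideal step) resolve identically in every row
  gtol <- 1e-9 * mag_max
  nz <- mag[mask & is.finite(mag) & mag > gtol]
  if (length(nz) == 0L) return(edges)
  th <- quantile(nz, c(low_q, high_q), names = FALSE)
  tm <- g$direction %% pi
  sector <- floor((tm + pi / 8) / (pi / 4)) %% 4
  magf <- mag
  magf[!mask | !is.finite(mag)] <- -Inf
  keep <- matrix(FALSE, nrow(values), ncol(values))
  for (s in 0:3) {
    dr <- nms_sectors[s + 1L, 1L]; dc <- nms_sectors[s + 1L, 2L]
    mp <- nbval(magf, dr, dc, fill = -Inf)
    mm <- nbval(magf, -dr, -dc, fill = -Inf)
    sel <- mask & !is.na(sector) & sector == s & is.finite(mag) & mag > gtol
    keep <- keep | (sel & mag >= mm - gtol & mag > mp + gtol)
  }
  strong <- keep & mag >= th[2]
  weak <- keep & mag >= th[1]
  edges <- strong
  repeat {
    nb <- matrix(FALSE, nrow(edges), ncol(edges))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- nb | nbval(edges, dr, dc, fill = FALSE)
    }
    grown <- weak & nb
    if (!any(grown & !edges)) break
    edges <- edges | grown
  }
  edges
}

#' Canny edge detection on a similarity map
#'
#' The full Canny chain: Gaussian smoothing (FWHM `fwhm_mm`), spatial
#' gradient, non-maximum suppression along the quantized gradient
#' direction, and hysteresis edge tracking. Because the pipeline is applied
#' to maps on different scales (Fisher z and eta squared), the hysteresis
#' thresholds are quantiles of the nonzero gradient magnitudes on the mask
#' rather than absolute values: pixels at or above the `high_q` quantile
#' seed edges, pixels at or above `low_q` extend them via 8-connectivity.
#' An all-flat map yields an empty edge map.
#'
#' @param map a [scalar_map()].
#' @param fwhm_mm smoothing width in millimetres.
#' @param pixel_mm pixel pitch; defaults to the map's own, else 2 mm.
#' @param low_q,high_q hysteresis threshold quantiles, `0 <= low_q <
#'   high_q <= 1`.
#' @param seed optional seed coordinate recorded in the result.
#' @return An `edge_map` (binary, thinned edges on the map's mask).
#' @export
canny_edges <- function(map, fwhm_mm = 6.0, pixel_mm = NULL,
                        low_q = 0.5, high_q = 0.9, seed = NULL) {
  stopifnot(inherits(map, "scalar_map"))
  if (!(low_q >= 0 && high_q <= 1 && low_q < high_q))
    stop("quantiles must satisfy 0 <= low_q < high_q <= 1")
  if (is.null(pixel_mm)) pixel_mm <- if (is.null(map$pixel_mm)) 2 else map$pixel_mm
  e <- canny_core(map$values, map$mask, fwhm_to_sigma_px(fwhm_mm, pixel_mm),
                  low_q, high_q)
  edge_map(e, map$mask, seed = seed)
}

#' Average binary edge maps into a probabilistic boundary map
#'
#' Each seed's Canny run gives a binary edge map; the per-pixel mean over
#' all seeds is the probabilistic boundary map, whose intensity at a pixel
#' is the fraction of seeds for which that pixel was detected as an edge.
#'
#' @param edge_maps non-empty list of `edge_map` objects with identical
#'   masks.
#' @return A [scalar_map()] of kind `"probability"`.
#' @export
probabilistic_boundary_map <- function(edge_maps) {
  if (length(edge_maps) == 0L) stop("need at least one edge map")
  mask <- edge_maps[[1]]$mask
  acc <- matrix(0, nrow(mask), ncol(mask))
  for (em in edge_maps) {
    if (!identical(em$mask, mask)) stop("edge maps have incongruent masks")
    acc <- acc + em$edges
  }
  v <- acc / length(edge_maps)
  v[!mask] <- NA_real_
  scalar_map(v, mask, kind = "probability")
}

# shared per-seed loop: `value_fn(i)` returns the i-th seed's similarity map
# as a plain matrix over the mask
pbm_over_seeds <- function(value_fn, mask, n_seeds, sigma_px, low_q, high_q) {
  acc <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(n_seeds))
    acc <- acc + canny_core(value_fn(i), mask, sigma_px, low_q, high_q)
  v <- acc / n_seeds
  v[!mask] <- NA_real_
  scalar_map(v, mask, kind = "probability")
}

#' Probabilistic boundary map by the local-timecourse (new) method
#'
#' For every masked pixel taken as seed, computes the seed-to-ROI Fisher-z
#' correlation map ([local_correlation_map()]) and runs Canny edge
#' detection on it; the binary edge maps are averaged over all seeds. Uses
#' only time series inside the region of interest.
#'
#' @param grid a preprocessed [ts_grid()] with at least 2 masked pixels.
#' @param fwhm_mm,low_q,high_q Canny parameters, see [canny_edges()].
#' @return A [scalar_map()] of kind `"probability"`.
#' @export
run_new_method <- function(grid, fwhm_mm = 6.0, low_q = 0.5, high_q = 0.9) {
  stopifnot(inherits(grid, "ts_grid"))
  if (sum(grid$mask) < 2L) stop("mask must contain at least 2 pixels")
  s <- grid_series(grid)
  idx <- attr(s, "index")
  check_variance(s, idx, dim(grid$mask))
  Z <- fisher_z(cor(t(s)))
  h <- nrow(grid$mask); w <- ncol(grid$mask)
  value_fn <- function(i) {
    v <- matrix(NA_real_, h, w)
    v[idx] <- Z[i, ]
    v
  }
  pbm_over_seeds(value_fn, grid$mask, length(idx),
                 fwhm_to_sigma_px(fwhm_mm, grid$pixel_mm), low_q, high_q)
}

#' Probabilistic boundary map by the standard (target-correlation) method
#'
#' For every masked pixel taken as seed, computes the eta-squared map of
#' its target-correlation profile against every other pixel's profile
#' ([eta2_map()]) and runs Canny edge detection on it; the binary edge maps
#' are averaged over all seeds. Gradient, edge and averaging steps share
#' their parameters with [run_new_method()].
#'
#' @param grid a preprocessed [ts_grid()].
#' @param targets a [target_set()] (whole-brain, gray-matter, contralateral
#'   or custom).
#' @param fwhm_mm,low_q,high_q Canny parameters, see [canny_edges()].
#' @return A [scalar_map()] of kind `"probability"`.
#' @export
run_standard_method <- function(grid, targets, fwhm_mm = 6.0,
                                low_q = 0.5, high_q = 0.9) {
  stopifnot(inherits(grid, "ts_grid"))
  if (!inherits(targets, "target_set") || nrow(targets$series) == 0L)
    stop("`targets` must be a non-empty target_set")
  if (sum(grid$mask) < 2L) stop("mask must contain at least 2 pixels")
  Z <- profile_matrix(grid, targets)
  idx <- which(grid$mask)
  rs <- rowSums(Z); rq <- rowSums(Z^2)
  h <- nrow(grid$mask); w <- ncol(grid$mask)
  value_fn <- function(i) {
    v <- matrix(NA_real_, h, w)
    v[idx] <- eta2_rows(Z[i, ], Z, rs, rq)
    v
  }
  pbm_over_seeds(value_fn, grid$mask, length(idx),
                 fwhm_to_sigma_px(fwhm_mm, grid$pixel_mm), low_q, high_q)
}
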