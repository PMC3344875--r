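#' Fisher z-transform of correlation coefficients
#'
#' Variance-stabilizing `atanh(r)`. Perfect correlations (the seed with
#' itself, or duplicated series) would map to infinity, so `|r|` is capped
#' at `r_cap` before the transform; this keeps every correlation map finite
#' without excluding the seed pixel.
#'
#' @param r numeric vector of correlations in `[-1, 1]` (a tolerance of
#'   1e-9 absorbs rounding).
#' @param r_cap cap applied to `|r|` before `atanh`; default 0.999
#'   (`atanh(0.999) = 3.8002`).
#' @return numeric vector of z values.
#' @export
fisher_z <- function(r, r_cap = 0.999) {
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE))
    stop("correlation outside [-1, 1]")
  atanh(pmin(pmax(r, -r_cap), r_cap))
}

# per-pixel standard deviations with an informative error for flat series
check_variance <- function(series, index, dims, what = "pixel") {
  sds <- apply(series, 1L, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    if (what == "pixel") {
      rc <- arrayInd(index[bad], dims)
      stop(sprintf("zero-variance series at pixel (row %d, col %d)",
                   rc[1], rc[2]))
    }
    stop(sprintf("zero-variance series at target %d", bad))
  }
  invisible(sds)
}

#' Seed-to-ROI local correlation map (new method front end)
#'
#' Correlates the seed pixel's time series with every masked pixel's series
#' and Fisher z-transforms the result. This is the front end of the
#' local-timecourse boundary mapping method: no information outside the
#' region of interest is used. The map is symmetric in seed and target
#' (the map seeded at `a` evaluated at `b` equals the map seeded at `b`
#' evaluated at `a`), and the seed's own value is the capped maximum z.
#'
#' @param grid a [ts_grid()] (preprocessed).
#' @param seed length-2 integer vector `(row, col)`, 1-based, on the mask.
#' @return A [scalar_map()] of kind `"fisher_z"`.
#' @export
local_correlation_map <- function(grid, seed) {
  stopifnot(inherits(grid, "ts_grid"), length(seed) == 2L)
  if (!isTRUE(grid$mask[seed[1], seed[2]]))
    stop("seed pixel is off the mask")
  s <- grid_series(grid)
  idx <- attr(s, "index")
  check_variance(s, idx, dim(grid$mask))
  seed_flat <- (seed[2] - 1L) * nrow(grid$mask) + seed[1]
  r <- as.vector(cor(s[match(seed_flat, idx), ], t(s)))
  v <- matrix(NA_real_, nrow(grid$mask), ncol(grid$mask))
  v[idx] <- fisher_z(r)
  scalar_map(v, grid$mask, kind = "fisher_z", pixel_mm = grid$pixel_mm)
}

#' Seed-to-target correlation profile (standard method front end)
#'
#' Fisher-z correlations between one seed's series and each series of a
#' target set, in the target set's stable order. The spatial pattern of
#' these profiles over seeds is what the standard boundary mapping method
#' compares with [eta2()].
#'
#' @param grid a [ts_grid()].
#' @param seed length-2 `(row, col)`, 1-based, on the mask.
#' @param targets a [target_set()] with series of length `T`.
#' @return An object of class `seed_profile`: list with `seed` and numeric
#'   `z`.
#' @export
target_correlation_profile <- function(grid, seed, targets) {
  stopifnot(inherits(grid, "ts_grid"), inherits(targets, "target_set"))
  if (ncol(targets$series) != dim(grid$data)[3])
    stop("target series length does not match the grid's T")
  if (!isTRUE(grid$mask[seed[1], seed[2]]))
    stop("seed pixel is off the mask")
  check_variance(targets$series, NULL, NULL, what = "target")
  x <- grid$data[seed[1], seed[2], ]
  if (sd(x) == 0)
    stop(sprintf("zero-variance series at pixel (row %d, col %d)",
                 seed[1], seed[2]))
  z <- fisher_z(as.vector(cor(x, t(targets$series))))
  structure(list(seed = seed, z = z), class = "seed_profile")
}

#' Eta-squared similarity between two paired profiles
#'
#' For profiles \eqn{a} and \eqn{b} of equal length, with per-position means
#' \eqn{m_i = (a_i + b_i)/2} and grand mean \eqn{M} of all values of both
#' profiles:
#' \deqn{\eta^2 = 1 - \frac{\sum_i (a_i - m_i)^2 + (b_i - m_i)^2}
#'                         {\sum_i (a_i - M)^2 + (b_i - M)^2}}
#' i.e. one minus the within-pair fraction of the total sum of squares.
#' Always in `[0, 1]`; equals 1 for identical profiles. Two constant, equal
#' profiles make the denominator zero; that degenerate case returns 1 with
#' a warning.
#'
#' @param a,b numeric vectors of equal length `>= 2`.
#' @return scalar in `[0, 1]`.
#' @export
eta2 <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  if (length(a) < 2L) stop("profiles must have length >= 2")
  m <- (a + b) / 2
  M <- mean(c(a, b))
  num <- sum((a - m)^2 + (b - m)^2)
  den <- sum((a - M)^2 + (b - M)^2)
  if (den == 0) {
    warning("both profiles constant and equal; eta2 defined as 1")
    return(1)
  }
  1 - num / den
}

# Fisher-z profile matrix: one row per masked pixel, one column per target
profile_matrix <- function(grid, targets) {
  s <- grid_series(grid)
  idx <- attr(s, "index")
  check_variance(s, idx, dim(grid$mask))
  check_variance(targets$series, NULL, NULL, what = "target")
  fisher_z(cor(t(s), t(targets$series)))
}

# eta2 of row `a` against every row of Z, vectorized via the identities
#   sum_i (a_i-m_i)^2+(b_i-m_i)^2 = sum_i (a_i-b_i)^2 / 2
#   sum_i (x_i-M)^2 = sum x^2 - 2 M sum x + m M^2
eta2_rows <- function(a, Z, row_sums = rowSums(Z), row_sq = rowSums(Z^2)) {
  m <- length(a)
  sa <- sum(a); sa2 <- sum(a * a)
  num <- 0.5 * (sa2 - 2 * as.vector(Z %*% a) + row_sq)
  M <- (sa / m + row_sums / m) / 2
  den <- (sa2 - 2 * M * sa + m * M^2) + (row_sq - 2 * M * row_sums + m * M^2)
  out <- ifelse(den > 0, 1 - num / den, 1)
  pmin(pmax(out, 0), 1)
}

#' Eta-squared similarity map for one seed (standard method)
#'
#' Computes the seed's target-correlation profile and the profile of every
#' other masked pixel, then maps the eta-squared similarity between the
#' seed's profile and each pixel's profile. Pixels in the same functional
#' area as the seed share its pattern of remote connectivity and score high;
#' the map drops abruptly across an areal border. The value at the seed
#' itself is 1, and the map is symmetric (seed `a`'s map at `b` equals seed
#' `b`'s map at `a`).
#'
#' @inheritParams target_correlation_profile
#' @return A [scalar_map()] of kind `"eta2"`.
#' @export
eta2_map <- function(grid, seed, targets) {
  stopifnot(inherits(grid, "ts_grid"))
  if (!isTRUE(grid$mask[seed[1], seed[2]]))
    stop("seed pixel is off the mask")
  Z <- profile_matrix(grid, targets)
  idx <- which(grid$mask)
  seed_flat <- (seed[2] - 1L) * nrow(grid$mask) + seed[1]
  e <- eta2_rows(Z[match(seed_flat, idx), ], Z)
  v <- matrix(NA_real_, nrow(grid$mask), ncol(grid$mask))
  v[idx] <- e
  scalar_map(v, grid$mask, kind = "eta2", pixel_mm = grid$pixel_mm)
}

#' Contralateral target set from a mirrored grid
#'
#' The standard method's cheapest target restriction: for every seed, the
#' pixels of the contralateral (mirrored) grid within `radius_mm` of the
#' mirrored seed location are collected, and the union over all seeds,
#' deduplicated, forms the target set. Mirroring is a left-right flip of the
#' column index; on a flat map the "spherical region" of the volumetric
#' formulation becomes an in-plane disc with its rim included
#' (distance <= radius).
#'
#' @param grid_contra a [ts_grid()] for the contralateral region (same
#'   pixel size).
#' @param seeds integer matrix of 1-based `(row, col)` seed coordinates,
#'   one row per seed.
#' @param radius_mm disc radius in millimetres (default 2).
#' @return A [target_set()] named `"contralateral"` with `coords`.
#' @export
contralateral_target_set <- function(grid_contra, seeds, radius_mm = 2.0) {
  stopifnot(inherits(grid_contra, "ts_grid"))
  seeds <- matrix(as.integer(seeds), ncol = 2L)
  h <- nrow(grid_contra$mask); w <- ncol(grid_contra$mask)
  px <- grid_contra$pixel_mm
  sel <- matrix(FALSE, h, w)
  rr <- ceiling(radius_mm / px)
  for (k in seq_len(nrow(seeds))) {
    r0 <- seeds[k, 1]; c0 <- w + 1L - seeds[k, 2]   # mirrored column
    for (i in max(1L, r0 - rr):min(h, r0 + rr))
      for (j in max(1L, c0 - rr):min(w, c0 + rr))
        if (grid_contra$mask[i, j] &&
            px * sqrt((i - r0)^2 + (j - c0)^2) <= radius_mm + 1e-9)
          sel[i, j] <- TRUE
  }
  idx <- which(sel)
  if (length(idx) == 0L)
    stop("contralateral target set is empty (mirrored seeds off-mask or radius too small)")
  d <- dim(grid_contra$data)
  flat <- matrix(grid_contra$data, d[1] * d[2], d[3])
  target_set(flat[idx, , drop = FALSE], name = "contralateral",
             coords = arrayInd(idx, c(h, w)))
}
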