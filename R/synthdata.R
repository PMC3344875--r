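# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Plant a parcellation on a flat-map grid
#'
#' Deterministic (given `seed`) assignment of an integer area label to each
#' pixel. `vertical_split` divides the grid at column `floor(width/2)`
#' (0-based; the border column belongs to the second area). `L_shape` gives
#' the lower-right quadrant its own label. `voronoi_k` samples `k` pixel
#' centers and labels each pixel by its nearest center (ties to the lowest
#' center index).
#'
#' @param height,width grid extent; split layouts need at least 10 x 10.
#' @param layout `"vertical_split"`, `"L_shape"` or `"voronoi_k"`.
#' @param k number of Voronoi cells (voronoi_k only).
#' @param seed RNG seed (used by voronoi_k).
#' @return integer label matrix (labels `1..K`).
#' @export
make_parcellation <- function(height, width,
                              layout = c("vertical_split", "L_shape",
                                         "voronoi_k"),
                              k = 4L, seed = 1L) {
  layout <- match.arg(layout)
  if (layout != "voronoi_k" && (height < 10L || width < 10L))
    stop("split layouts need a grid of at least 10 x 10")
  labels <- matrix(1L, height, width)
  if (layout == "vertical_split") {
    border <- width %/% 2L          # 0-based border column
    labels[, (border + 1L):width] <- 2L
  } else if (layout == "L_shape") {
    labels[(height %/% 2L + 1L):height, (width %/% 2L + 1L):width] <- 2L
  } else {
    if (k > height * width) stop("k exceeds the number of pixels")
    centers <- with_seed(seed, sample.int(height * width, k))
    crc <- arrayInd(centers, c(height, width))
    for (i in seq_len(height)) for (j in seq_len(width)) {
      d2 <- (crc[, 1] - i)^2 + (crc[, 2] - j)^2
      labels[i, j] <- which.min(d2)
    }
  }
  labels
}

#' True boundary pixels of a planted parcellation
#'
#' A pixel is a true boundary pixel when at least one of its 4-neighbors
#' (on the mask) carries a different label.
#'
#' @param labels integer label matrix.
#' @param mask optional logical matrix; default all `TRUE`.
#' @return logical matrix.
#' @export
true_boundary_pixels <- function(labels, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(labels), ncol(labels))
  lab <- labels
  lab[!mask] <- NA_integer_
  out <- matrix(FALSE, nrow(labels), ncol(labels))
  for (o in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
    nb <- nbval(lab, o[1], o[2])
    out <- out | (!is.na(lab) & !is.na(nb) & nb != lab)
  }
  out
}

#' Generate latent band-limited network signals
#'
#' `K` mutually orthogonal, unit-variance, band-limited signals standing in
#' for the large-scale network fluctuations that drive resting-state
#' correlations. White Gaussian noise is band-passed by an ideal FFT mask
#' (so all power lies inside the band, where the analysis looks),
#' orthogonalized by QR, and standardized.
#'
#' @param K number of networks; must satisfy `K <= T/4`.
#' @param T_len number of time points (>= 64).
#' @param tr_seconds sampling interval in seconds.
#' @param band two-sided frequency band in Hz (default the resting-state
#'   band 0.009-0.08 Hz).
#' @param seed RNG seed.
#' @return `K x T_len` numeric matrix, one signal per row.
#' @export
make_network_signals <- function(K, T_len, tr_seconds = 3.0,
                                 band = c(0.009, 0.08), seed = 1L) {
  if (T_len < 64L) stop("T_len must be at least 64")
  if (K > T_len / 4) stop("K must not exceed T_len / 4")
  fs <- 1 / tr_seconds
  if (band[2] >= fs / 2)
    stop("band upper edge at or above Nyquist for this TR")
  with_seed(seed, {
    W <- matrix(rnorm(T_len * K), T_len, K)
    B <- apply(W, 2L, fft_bandlimit, fs = fs, f_low = band[1], f_high = band[2])
    Q <- qr.Q(qr(B))
    Q <- sweep(Q, 2L, apply(Q, 2L, sd), "/")
    t(Q)
  })
}

# band-limited unit-variance iid noise, one series per row
make_noise <- function(n, T_len, fs, band) {
  W <- matrix(rnorm(n * T_len), n, T_len)
  N <- t(apply(W, 1L, fft_bandlimit, fs = fs, f_low = band[1], f_high = band[2]))
  N / apply(N, 1L, sd)
}

#' Synthesize a flat-map time-series grid from a planted parcellation
#'
#' Every pixel's series is `sqrt(w) * network(label) + sqrt(1 - w) * noise`,
#' standardized, where the noise is independent per pixel and band-limited
#' like the networks (so boundaries arise from network membership, not from
#' spectral artifacts). The expected correlation between two pixels of the
#' same area is `w`; between areas it is 0 (networks are orthogonal).
#'
#' @param labels integer label matrix from [make_parcellation()].
#' @param networks `K x T` signal matrix from [make_network_signals()];
#'   every label must index a row.
#' @param w mixing weight in `[0, 1]`.
#' @param noise_seed RNG seed for the pixel noise.
#' @param tr_seconds,pixel_mm,band acquisition metadata / noise band.
#' @param mask optional logical matrix; default all `TRUE`.
#' @return A [ts_grid()].
#' @export
make_grid <- function(labels, networks, w = 0.5, noise_seed = 1L,
                      tr_seconds = 3.0, pixel_mm = 2.0,
                      band = c(0.009, 0.08), mask = NULL) {
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  if (max(labels) > nrow(networks) || min(labels) < 1L)
    stop("label without a matching network row")
  h <- nrow(labels); wd <- ncol(labels)
  T_len <- ncol(networks)
  fs <- 1 / tr_seconds
  series <- with_seed(noise_seed, {
    N <- make_noise(h * wd, T_len, fs, band)
    S <- sqrt(w) * networks[as.vector(labels), , drop = FALSE] +
      sqrt(1 - w) * N
    S / apply(S, 1L, sd)
  })
  ts_grid(array(series, c(h, wd, T_len)), mask = mask,
          tr_seconds = tr_seconds, pixel_mm = pixel_mm,
          meta = list(synthetic = TRUE, w = w, noise_seed = noise_seed))
}

#' Synthesize a target set of remote same-network nodes
#'
#' Emulates the standard method's external targets (e.g. whole-brain or
#' contralateral voxels): for each network, `n_per_network` series are
#' built exactly like grid pixels (`sqrt(w) * network + sqrt(1-w) * noise`,
#' standardized), representing distant nodes that share that network's
#' fluctuation.
#'
#' @param networks `K x T` matrix from [make_network_signals()].
#' @param n_per_network targets per network (default 16).
#' @param w mixing weight (default 0.5).
#' @param seed RNG seed.
#' @param tr_seconds,band noise parameters matching the grid.
#' @return A [target_set()] (network-major order).
#' @export
make_target_set <- function(networks, n_per_network = 16L, w = 0.5,
                            seed = 1L, tr_seconds = 3.0,
                            band = c(0.009, 0.08)) {
  K <- nrow(networks); T_len <- ncol(networks)
  fs <- 1 / tr_seconds
  series <- with_seed(seed, {
    N <- make_noise(K * n_per_network, T_len, fs, band)
    S <- sqrt(w) * networks[rep(seq_len(K), each = n_per_network), ,
                            drop = FALSE] + sqrt(1 - w) * N
    S / apply(S, 1L, sd)
  })
  target_set(series, name = "custom")
}

#' Simulate a complete flat-map boundary-mapping study
#'
#' One call producing everything the pipeline consumes: a parcellated grid
#' of time series, the planted truth (labels, true boundary pixels, latent
#' networks), a target set for the standard method, and optionally a
#' matched contralateral grid (mirrored labels, shared networks,
#' independent noise — modeling the premise that a region's strongest
#' remote connectivity is with its contralateral homologue). Fully
#' deterministic given `seed`.
#'
#' The defaults are the package's reference study conditions: a 25 x 25
#' grid of 2-mm pixels (a 50 mm x 50 mm flat map), TR 3 s, T = 512 frames,
#' a vertical two-area split, mixing weight `w = 0.5`, and the
#' 0.009-0.08 Hz band.
#'
#' @param height,width,layout,k see [make_parcellation()].
#' @param t_len time points.
#' @param w mixing weight.
#' @param tr_seconds,pixel_mm,band acquisition parameters.
#' @param n_targets_per_network targets per network for the standard
#'   method.
#' @param contralateral also generate the mirrored contralateral grid.
#' @param seed master RNG seed; sub-seeds are derived by fixed offsets.
#' @return object of class `flatmap_sim`: list with `grid`, `truth`
#'   (class `synthetic_truth`: `labels`, `true_boundary`, `networks`, `w`,
#'   `seed`), `targets`, and optionally `contra`.
#' @export
simulate_flatmap <- function(height = 25L, width = 25L, t_len = 512L,
                             layout = "vertical_split", k = 4L, w = 0.5,
                             tr_seconds = 3.0, pixel_mm = 2.0,
                             band = c(0.009, 0.08),
                             n_targets_per_network = 16L,
                             contralateral = FALSE, seed = 1L) {
  labels <- make_parcellation(height, width, layout, k = k, seed = seed)
  K <- max(labels)
  networks <- make_network_signals(K, t_len, tr_seconds, band,
                                   seed = seed + 1L)
  grid <- make_grid(labels, networks, w = w, noise_seed = seed + 2L,
                    tr_seconds = tr_seconds, pixel_mm = pixel_mm, band = band)
  targets <- make_target_set(networks, n_per_network = n_targets_per_network,
                             w = w, seed = seed + 3L,
                             tr_seconds = tr_seconds, band = band)
  truth <- structure(list(labels = labels,
                          true_boundary = true_boundary_pixels(labels),
                          networks = networks, w = w, seed = seed),
                     class = "synthetic_truth")
  out <- list(grid = grid, truth = truth, targets = targets)
  if (isTRUE(contralateral)) {
    out$contra <- make_grid(labels[, ncol(labels):1, drop = FALSE], networks,
                            w = w, noise_seed = seed + 4L,
                            tr_seconds = tr_seconds, pixel_mm = pixel_mm,
                            band = band)
  }
  structure(out, class = "flatmap_sim")
}

#' @export
print.flatmap_sim <- function(x, ...) {
  d <- dim(x$grid$data)
  cat(sprintf("flatmap_sim: %d x %d grid, T = %d, %d areas, w = %g, seed = %d\n",
              d[1], d[2], d[3], max(x$truth$labels), x$truth$w, x$truth$seed))
  invisible(x)
}
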