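# directional offsets used by the ridge classifier: horizontal, vertical,
# diagonal "\" (down-right), diagonal "/" (up-right); a direction's two
# neighbors are +/- the offset
class_dirs <- list(h  = c(0L, 1L),
                   v  = c(1L, 0L),
                   d1 = c(1L, 1L),
                   d2 = c(1L, -1L))
class_orth <- c(h = "v", v = "h", d1 = "d2", d2 = "d1")

#' Classify probabilistic-boundary-map pixels as Boundary / Background
#'
#' Ridge-based labeling of a probabilistic boundary map. For each masked
#' pixel, its local direction is chosen among horizontal, vertical and the
#' two diagonals by summing the three linear pixel values (the pixel and
#' its two neighbors) along each direction and taking the greatest (ties
#' resolved by the fixed precedence horizontal > vertical > diagonal-down >
#' diagonal-up; off-mask neighbors are omitted from the sums). The pixel
#' is a ridge candidate when its value is strictly greater than both
#' neighbors orthogonal to that direction; the comparison requires the
#' full orthogonal triple, so a pixel whose orthogonal neighbor falls off
#' the mask cannot be a candidate (otherwise every mask-border pixel could
#' win its one-sided comparison by default). Candidates that
#' form an 8-connected run of three or more become Boundary pixels. A pixel
#' is Background when none of its eight surrounding pixels is a Boundary
#' pixel; everything else is Neither. Pixels with no on-mask neighbor at
#' all are Neither.
#'
#' @param pbm a [scalar_map()] (normally of kind `"probability"`).
#' @return character matrix with entries `"Boundary"`, `"Background"`,
#'   `"Neither"` (off-mask pixels `NA`).
#' @seealso [snr()], [boundary_evaluation()]
#' @export
classify_boundary_pixels <- function(pbm) {
  stopifnot(inherits(pbm, "scalar_map"))
  v <- pbm$values
  mask <- pbm$mask
  v[!mask] <- NA_real_
  h <- nrow(v); w <- ncol(v)

  nb <- lapply(class_dirs, function(o)
    list(p = nbval(v, o[1], o[2]), m = nbval(v, -o[1], -o[2])))
  zero_na <- function(x) ifelse(is.na(x), 0, x)
  sums <- lapply(nb, function(x) v + zero_na(x$p) + zero_na(x$m))

  dir_idx <- matrix(NA_integer_, h, w)
  best <- matrix(-Inf, h, w)
  for (d in seq_along(sums)) {          # precedence = list order h,v,d1,d2
    better <- mask & !is.na(sums[[d]]) & sums[[d]] > best
    dir_idx[better] <- d
    best[better] <- sums[[d]][better]
  }

  # per-direction "strictly greater than both orthogonal neighbors";
  # the full triple must lie on the mask
  cand_for <- lapply(nb, function(x)
    !is.na(x$p) & !is.na(x$m) & v > x$p & v > x$m)
  candidate <- matrix(FALSE, h, w)
  for (d in seq_along(class_dirs)) {
    o <- match(class_orth[[d]], names(class_dirs))
    sel <- mask & !is.na(dir_idx) & dir_idx == d
    candidate[sel] <- cand_for[[o]][sel]
  }

  has_any_nb <- matrix(FALSE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    has_any_nb <- has_any_nb | nbval(mask, dr, dc, fill = FALSE)
  }
  candidate <- candidate & has_any_nb

  boundary <- contiguous_of_size(candidate, min_size = 3L)

  bnd_nb <- matrix(FALSE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    bnd_nb <- bnd_nb | nbval(boundary, dr, dc, fill = FALSE)
  }

  labels <- matrix(NA_character_, h, w)
  labels[mask] <- "Neither"
  labels[mask & !boundary & !bnd_nb & has_any_nb] <- "Background"
  labels[boundary] <- "Boundary"
  labels[mask & !has_any_nb] <- "Neither"
  labels
}

# keep only pixels of 8-connected components of size >= min_size
contiguous_of_size <- function(bin, min_size = 3L) {
  h <- nrow(bin); w <- ncol(bin)
  out <- matrix(FALSE, h, w)
  seen <- matrix(FALSE, h, w)
  idx <- which(bin)
  for (start in idx) {
    if (seen[start]) next
    queue <- start
    comp <- integer(0)
    seen[start] <- TRUE
    while (length(queue) > 0L) {
      p <- queue[1]; queue <- queue[-1]
      comp <- c(comp, p)
      pr <- (p - 1L) %% h + 1L; pc <- (p - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        nr <- pr + dr; nc <- pc + dc
        if (nr < 1L || nr > h || nc < 1L || nc > w) next
        q <- (nc - 1L) * h + nr
        if (bin[q] && !seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
      }
    }
    if (length(comp) >= min_size) out[comp] <- TRUE
  }
  out
}

#' Boundary signal-to-noise ratio of a probabilistic boundary map
#'
#' Mean probability over Boundary pixels divided by mean probability over
#' Background pixels (see [classify_boundary_pixels()]). Scale-invariant in
#' the map values.
#'
#' @param pbm a [scalar_map()].
#' @param labels optional label matrix from [classify_boundary_pixels()];
#'   computed from `pbm` if omitted.
#' @return positive scalar.
#' @export
snr <- function(pbm, labels = NULL) {
  if (is.null(labels)) labels <- classify_boundary_pixels(pbm)
  b <- pbm$values[!is.na(labels) & labels == "Boundary"]
  g <- pbm$values[!is.na(labels) & labels == "Background"]
  if (length(b) == 0L) stop("no Boundary pixels; SNR undefined")
  if (length(g) == 0L) stop("no Background pixels; SNR undefined")
  mb <- mean(b); mg <- mean(g)
  if (mg == 0) stop("Background mean is zero; SNR undefined")
  mb / mg
}

#' Full Boundary/Background evaluation of a probabilistic boundary map
#'
#' Bundles [classify_boundary_pixels()] and [snr()].
#'
#' @param pbm a [scalar_map()].
#' @return object of class `boundary_eval`: list with `labels`, `snr`,
#'   `n_boundary`, `n_background`. `snr` is `NA` (with a warning) when
#'   either pixel class is empty.
#' @export
boundary_evaluation <- function(pbm) {
  labels <- classify_boundary_pixels(pbm)
  s <- tryCatch(snr(pbm, labels), error = function(e) {
    warning(conditionMessage(e))
    NA_real_
  })
  structure(list(labels = labels, snr = s,
                 n_boundary = sum(labels == "Boundary", na.rm = TRUE),
                 n_background = sum(labels == "Background", na.rm = TRUE)),
            class = "boundary_eval")
}

#' @export
print.boundary_eval <- function(x, ...) {
  cat(sprintf("boundary_eval: %d Boundary, %d Background pixels, SNR = %.3f\n",
              x$n_boundary, x$n_background, x$snr))
  invisible(x)
}

# isotropic spatial autocorrelation at integer lag k: Pearson correlation of
# value pairs offset by k along rows and along columns, pooled
spatial_autocorr <- function(values, mask, k) {
  xs <- numeric(0); ys <- numeric(0)
  for (o in list(c(0L, k), c(k, 0L))) {
    nv <- nbval(values, o[1], o[2])
    nm <- nbval(mask, o[1], o[2], fill = FALSE)
    ok <- mask & nm & !is.na(values) & !is.na(nv)
    xs <- c(xs, values[ok]); ys <- c(ys, nv[ok])
  }
  if (length(xs) < 3L || sd(xs) == 0 || sd(ys) == 0) return(0)
  cor(xs, ys)
}

#' Similarity of two maps with autocorrelation-corrected degrees of freedom
#'
#' Pearson correlation of two scalar maps over their shared mask, tested
#' with effective degrees of freedom reduced for spatial autocorrelation
#' (smoothed maps carry far fewer independent samples than pixels). The
#' Bartlett correction factor is the isotropic lag-product form
#' `BCF = 1 + 2 * sum_k rho_a(k) * rho_b(k)`, where `rho(k)` is the map's
#' spatial autocorrelation at integer pixel lag `k` (pairs pooled over row
#' and column offsets); the sum accumulates from lag 1 while either
#' autocorrelation is at or above `rho_threshold`. BCF is clamped at >= 1,
#' so `dof_effective = n / BCF - 2 <= n - 2`. The test statistic is
#' `t = r * sqrt(dof / (1 - r^2))` with a two-sided p-value from the t
#' distribution on `dof_effective`.
#'
#' @param map_a,map_b [scalar_map()]s with identical masks (>= 10 shared
#'   pixels).
#' @param rho_threshold stop accumulating lags once both autocorrelations
#'   drop below this value (default 0.1).
#' @param force_bcf override the correction factor (e.g. `1` recovers the
#'   classical `n - 2` dof test).
#' @return object of class `map_similarity`: list with `r`,
#'   `dof_effective`, `t_statistic`, `p_value`, `bcf`, `n`.
#' @export
compare_maps <- function(map_a, map_b, rho_threshold = 0.1, force_bcf = NULL) {
  stopifnot(inherits(map_a, "scalar_map"), inherits(map_b, "scalar_map"))
  if (!identical(map_a$mask, map_b$mask)) stop("maps have incongruent masks")
  mask <- map_a$mask
  n <- sum(mask)
  if (n < 10L) stop("need at least 10 shared mask pixels")
  va <- map_a$values[mask]; vb <- map_b$values[mask]
  if (sd(va) == 0 || sd(vb) == 0) stop("constant map; correlation undefined")
  r <- cor(va, vb)
  if (is.null(force_bcf)) {
    max_lag <- min(dim(mask)) - 2L
    s <- 0
    for (k in seq_len(max_lag)) {
      ra <- spatial_autocorr(map_a$values, mask, k)
      rb <- spatial_autocorr(map_b$values, mask, k)
      if (ra < rho_threshold && rb < rho_threshold) break
      s <- s + ra * rb
    }
    bcf <- max(1, 1 + 2 * s)
  } else {
    bcf <- force_bcf
  }
  dof <- n / bcf - 2
  if (dof < 1) {
    warning("effective dof below 1; clamped")
    dof <- 1
  }
  tstat <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(dof / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = dof)
  structure(list(r = r, dof_effective = dof, t_statistic = tstat,
                 p_value = p, bcf = bcf, n = n),
            class = "map_similarity")
}

#' @export
print.map_similarity <- function(x, ...) {
  cat(sprintf("map similarity: r = %.3f, t(%.1f) = %.2f, p = %.3g (BCF = %.2f, n = %d)\n",
              x$r, x$dof_effective, x$t_statistic, x$p_value, x$bcf, x$n))
  invisible(x)
}

#' Correlation profiles along a line crossing a boundary
#'
#' For a line of pixels crossing a putative areal boundary, computes, for
#' each line pixel taken as seed, its correlation with every pixel of the
#' line. Each profile peaks at its own seed; on a genuine boundary the
#' profiles split into two groups, similar within each delineated area and
#' dissimilar across the boundary.
#'
#' @param grid a [ts_grid()].
#' @param line integer matrix (>= 8 rows) of 1-based `(row, col)` pixel
#'   coordinates, all on the mask.
#' @param reference optional index (into the line) or `(row, col)` of a
#'   reference pixel, stored for plotting.
#' @return object of class `cross_profile`: list with the `n x n`
#'   correlation matrix `profiles` (row i = seed i's profile), `line`,
#'   `reference`.
#' @export
cross_boundary_profile <- function(grid, line, reference = NULL) {
  stopifnot(inherits(grid, "ts_grid"))
  line <- matrix(as.integer(line), ncol = 2L)
  if (nrow(line) < 8L) stop("line must contain at least 8 pixels")
  on <- grid$mask[line]
  if (!all(on))
    stop("line pixels off the mask: ",
         paste(sprintf("(%d,%d)", line[!on, 1], line[!on, 2]), collapse = " "))
  s <- t(vapply(seq_len(nrow(line)),
                function(i) grid$data[line[i, 1], line[i, 2], ],
                numeric(dim(grid$data)[3])))
  structure(list(profiles = cor(t(s)), line = line, reference = reference),
            class = "cross_profile")
}

#' @export
plot.cross_profile <- function(x, ...) {
  n <- nrow(x$profiles)
  plot(NA, xlim = c(1, n), ylim = range(x$profiles), xlab = "line position",
       ylab = "correlation", ...)
  for (i in seq_len(n)) lines(seq_len(n), x$profiles[i, ], col = i)
  invisible(x)
}
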