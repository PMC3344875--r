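#' Fit a probabilistic areal boundary map to a flat-map grid
#'
#' Main entry point of the package. Runs the full boundary-mapping pipeline
#' on a (preprocessed) flat-map grid of resting-state time series and
#' returns a classed result holding the probabilistic boundary map and the
#' parameters of the run.
#'
#' Two methods are available. `"local"` (the local-timecourse method) uses
#' only the time series inside the region of interest: each pixel in turn
#' seeds a seed-to-ROI Fisher-z correlation map. `"standard"` correlates
#' each seed against an external `target_set` and compares the resulting
#' profiles across pixels with the eta-squared statistic. Both similarity
#' maps then pass through the same Canny edge detector (Gaussian smoothing
#' at `fwhm_mm`, gradient, non-maximum suppression, quantile-based
#' hysteresis), and the per-seed binary edge maps are averaged into the
#' probabilistic boundary map.
#'
#' @param grid a [ts_grid()], normally already passed through [bandpass()]
#'   and [nuisance_regress()].
#' @param method `"local"` or `"standard"`.
#' @param targets a [target_set()]; required for the standard method.
#' @param fwhm_mm Canny smoothing width in millimetres (default 6).
#' @param low_q,high_q hysteresis threshold quantiles (defaults 0.5, 0.9).
#' @return object of class `boundary_map`: list with elements `pbm` (a
#'   probability [scalar_map()]), `method`, `params`, `n_seeds`, `call`.
#' @examples
#' sim <- simulate_flatmap(height = 12, width = 12, t_len = 96, seed = 1)
#' fit <- boundary_map(sim$grid, method = "local")
#' summary(fit)
#' @export
boundary_map <- function(grid, method = c("local", "standard"),
                         targets = NULL, fwhm_mm = 6.0,
                         low_q = 0.5, high_q = 0.9) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "ts_grid"))
  if (method == "standard" && is.null(targets))
    stop("the standard method requires a `target_set`")
  pbm <- if (method == "local") {
    run_new_method(grid, fwhm_mm = fwhm_mm, low_q = low_q, high_q = high_q)
  } else {
    run_standard_method(grid, targets, fwhm_mm = fwhm_mm,
                        low_q = low_q, high_q = high_q)
  }
  structure(list(pbm = pbm, method = method,
                 params = list(fwhm_mm = fwhm_mm, low_q = low_q,
                               high_q = high_q,
                               pixel_mm = grid$pixel_mm,
                               tr_seconds = grid$tr_seconds,
                               targets = if (is.null(targets)) NULL else
                                 list(name = targets$name,
                                      n = nrow(targets$series))),
                 n_seeds = sum(grid$mask), call = match.call()),
            class = "boundary_map")
}

#' @export
print.boundary_map <- function(x, ...) {
  cat(sprintf("boundary_map (%s method): %d seeds, %d x %d grid\n",
              x$method, x$n_seeds, nrow(x$pbm$values), ncol(x$pbm$values)))
  cat(sprintf("  Canny: FWHM %g mm, hysteresis quantiles (%.2g, %.2g)\n",
              x$params$fwhm_mm, x$params$low_q, x$params$high_q))
  if (!is.null(x$params$targets))
    cat(sprintf("  targets: %s (n = %d)\n", x$params$targets$name,
                x$params$targets$n))
  v <- x$pbm$values[x$pbm$mask]
  cat(sprintf("  boundary probability range [%.3f, %.3f]\n", min(v), max(v)))
  invisible(x)
}

#' @export
summary.boundary_map <- function(object, ...) {
  ev <- boundary_evaluation(object$pbm)
  structure(list(fit = object, evaluation = ev),
            class = "summary.boundary_map")
}

#' @export
print.summary.boundary_map <- function(x, ...) {
  print(x$fit)
  print(x$evaluation)
  invisible(x)
}

#' @export
plot.boundary_map <- function(x, main = NULL, ...) {
  if (is.null(main))
    main <- sprintf("probabilistic boundary map (%s)", x$method)
  plot(x$pbm, main = main, ...)
  invisible(x)
}

#' @export
coef.boundary_map <- function(object, ...) object$pbm$values
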