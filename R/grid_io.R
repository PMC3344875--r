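#' Construct a flat-map time-series grid
#'
#' A `ts_grid` holds one BOLD (or arbitrary) time series per pixel of a 2D
#' flat-map grid, together with a pixel mask delimiting the region of
#' interest, the sampling interval (TR) and the pixel pitch. All analysis
#' functions in the package consume this container and ignore every pixel
#' outside the mask.
#'
#' @param data numeric array of dimension `height x width x T` (row, col,
#'   time). `T` must be at least 8.
#' @param mask logical matrix `height x width`; `NULL` means every pixel
#'   whose series is entirely finite.
#' @param tr_seconds sampling interval in seconds (> 0).
#' @param pixel_mm pixel pitch in millimetres (> 0). Defaults to 2, the
#'   in-plane resolution of a 50 mm x 50 mm flat map sampled at 2 mm.
#' @param meta free-form named list of provenance information.
#' @return An object of class `ts_grid`.
#' @seealso [read_grid()], [write_grid()], [boundary_map()]
#' @export
ts_grid <- function(data, mask = NULL, tr_seconds, pixel_mm = 2, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (row, col, time)")
  d <- dim(data)
  if (d[3] < 8L) stop("time dimension must be at least 8 (got ", d[3], ")")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || !is.finite(tr_seconds) ||
      tr_seconds <= 0)
    stop("`tr_seconds` must be a positive number")
  if (!is.numeric(pixel_mm) || length(pixel_mm) != 1L || pixel_mm <= 0)
    stop("`pixel_mm` must be a positive number")
  if (is.null(mask)) {
    mask <- apply(is.finite(data), c(1L, 2L), all)
  }
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    stop("`mask` must be a logical matrix with the same (row, col) extent as `data`")
  mask[is.na(mask)] <- FALSE
  structure(list(data = data, mask = mask, tr_seconds = as.numeric(tr_seconds),
                 pixel_mm = as.numeric(pixel_mm), meta = meta),
            class = "ts_grid")
}

#' @export
print.ts_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ts_grid: %d x %d grid, T = %d, %d/%d pixels on mask\n",
              d[1], d[2], d[3], sum(x$mask), d[1] * d[2]))
  cat(sprintf("  TR = %g s, pixel = %g mm\n", x$tr_seconds, x$pixel_mm))
  invisible(x)
}

#' @export
dim.ts_grid <- function(x) dim(x$data)

# Masked series as an n_masked x T matrix, pixels in column-major mask order.
# This ordering is the package-wide convention for flattening the mask.
grid_series <- function(grid) {
  idx <- which(grid$mask)
  d <- dim(grid$data)
  m <- matrix(grid$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
  attr(m, "index") <- idx
  m
}

# replace masked series from an n_masked x T matrix (inverse of grid_series)
grid_replace_series <- function(grid, series) {
  d <- dim(grid$data)
  flat <- matrix(grid$data, d[1] * d[2], d[3])
  flat[which(grid$mask), ] <- series
  grid$data <- array(flat, d)
  grid$data[array(rep(!grid$mask, d[3]), d)] <- NA_real_
  grid
}

#' Construct a scalar map over a flat-map mask
#'
#' @param values numeric matrix; entries off the mask are set to `NA`.
#' @param mask logical matrix, same extent.
#' @param kind one of `"fisher_z"`, `"eta2"`, `"gradient"`, `"probability"`.
#'   Probability and eta2 maps must lie in `[0, 1]` on the mask.
#' @param pixel_mm optional pixel pitch carried for smoothing convenience.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, mask, kind = c("fisher_z", "eta2", "gradient",
                                              "probability"),
                       pixel_mm = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !identical(dim(values), dim(mask)))
    stop("`values` and `mask` must be matrices of identical extent")
  values[!mask] <- NA_real_
  v <- values[mask]
  if (kind %in% c("probability", "eta2")) {
    ok <- is.na(v) | (v >= -1e-12 & v <= 1 + 1e-12)
    if (!all(ok))
      stop(sprintf("%s map values must lie in [0, 1]", kind))
    values[mask] <- pmin(pmax(values[mask], 0), 1)
  }
  structure(list(values = values, mask = mask, kind = kind,
                 pixel_mm = pixel_mm),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("scalar_map (%s): %d x %d, %d mask pixels, range [%.4g, %.4g]\n",
              x$kind, nrow(x$values), ncol(x$values), sum(x$mask),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.scalar_map <- function(x, main = x$kind, ...) {
  v <- x$values
  v[!x$mask] <- NA
  # image() draws x along rows; transpose and flip so row 1 is on top
  image(t(v)[, nrow(v):1, drop = FALSE], col = gray(seq(0, 1, length.out = 256)),
        axes = FALSE, main = main, ...)
  box()
  invisible(x)
}

# binary edge map from one seed's Canny run
edge_map <- function(edges, mask, seed = NULL) {
  stopifnot(is.logical(edges), identical(dim(edges), dim(mask)))
  edges[!mask] <- FALSE
  structure(list(edges = edges, mask = mask, seed = seed), class = "edge_map")
}

#' Construct a target time-series set for the standard method
#'
#' The standard boundary-mapping analysis correlates each seed against an
#' external collection of target series (in the original formulation: every
#' voxel of the whole brain; restricted variants use the cortical gray
#' matter or the contralateral homologue of the region of interest).
#'
#' @param series numeric matrix, one row per target, `T` columns.
#' @param name one of `"whole"`, `"gray_matter"`, `"contralateral"`,
#'   `"custom"`.
#' @param coords optional integer matrix of (row, col) provenance
#'   coordinates, one row per target.
#' @return An object of class `target_set`.
#' @export
target_set <- function(series, name = c("custom", "whole", "gray_matter",
                                        "contralateral"),
                       coords = NULL) {
  name <- match.arg(name)
  if (!is.matrix(series) || nrow(series) < 1L)
    stop("`series` must be a non-empty matrix (targets x time)")
  if (!is.null(coords) && nrow(coords) != nrow(series))
    stop("`coords` must have one row per target")
  structure(list(name = name, series = series, coords = coords),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("target_set '%s': %d targets, T = %d\n", x$name,
              nrow(x$series), ncol(x$series)))
  invisible(x)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a time-series grid to disk
#'
#' Delimited output is a TSV with comment header lines recording the grid
#' extent, TR and pixel size, then one line per masked pixel holding the
#' 0-based `row` and `col` indices followed by the `T` series values at full
#' precision (`%.17g`, bit-exact round trip). NIfTI output is an
#' `X x Y x 1 x T` volume with off-mask pixels stored as `NaN`.
#'
#' @param grid a [ts_grid()].
#' @param path output file path.
#' @param format `"delimited"` or `"nifti"`.
#' @export
write_grid <- function(grid, path, format = c("delimited", "nifti")) {
  format <- match.arg(format)
  d <- dim(grid$data)
  if (format == "nifti") {
    arr <- grid$data
    arr[array(rep(!grid$mask, d[3]), d)] <- NaN
    RNifti::writeNifti(RNifti::asNifti(array(arr, c(d[1], d[2], 1L, d[3]))),
                       path)
    return(invisible(NULL))
  }
  s <- grid_series(grid)
  idx <- attr(s, "index")
  rc <- arrayInd(idx, d[1:2])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# arealmap grid v1",
               sprintf("# height=%d width=%d tr_seconds=%s pixel_mm=%s",
                       d[1], d[2], fmt17(grid$tr_seconds), fmt17(grid$pixel_mm)),
               paste(c("row", "col", paste0("t", seq_len(d[3]))),
                     collapse = "\t")), con)
  body <- vapply(seq_len(nrow(s)), function(i) {
    paste(c(rc[i, 1] - 1L, rc[i, 2] - 1L, fmt17(s[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(NULL)
}

parse_header_fields <- function(lines) {
  out <- list()
  for (ln in lines) {
    for (tok in strsplit(sub("^#\\s*", "", ln), "\\s+")[[1]]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2L) {
        v <- suppressWarnings(as.numeric(kv[2]))
        if (!is.na(v)) out[[kv[1]]] <- v
      }
    }
  }
  out
}

#' Read a time-series grid from disk
#'
#' Accepts the delimited format written by [write_grid()] (0-based row/col
#' indices; missing pixels are off-mask) or a NIfTI-1 volume of shape
#' `X x Y x T` or `X x Y x 1 x T` (the singleton third dimension is
#' dropped; pixels with any non-finite value are off-mask). For NIfTI input
#' `tr_seconds` must be supplied; for delimited input explicit arguments
#' override the values recorded in the file header.
#'
#' @param path input file path.
#' @param format `"delimited"` or `"nifti"`.
#' @param tr_seconds,pixel_mm acquisition metadata; see Details.
#' @param mask optional logical matrix overriding the inferred mask.
#' @return A [ts_grid()].
#' @export
read_grid <- function(path, format = c("delimited", "nifti"),
                      tr_seconds = NULL, pixel_mm = NULL, mask = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "nifti") {
    arr <- as.array(RNifti::readNifti(path))
    d <- dim(arr)
    if (length(d) == 4L) {
      if (d[3] != 1L) stop("expected a flat-map NIfTI with singleton third dimension")
      arr <- array(arr, c(d[1], d[2], d[4]))
    } else if (length(d) != 3L) {
      stop("expected a 3D or 4D NIfTI volume")
    }
    if (is.null(tr_seconds)) stop("`tr_seconds` is required for NIfTI input")
    return(ts_grid(arr, mask = mask, tr_seconds = tr_seconds,
                   pixel_mm = if (is.null(pixel_mm)) 2 else pixel_mm,
                   meta = list(source = path)))
  }
  lines <- readLines(path)
  hdr <- parse_header_fields(lines[startsWith(lines, "#")])
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("no pixel rows in ", path)
  toks <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(toks)
  if (length(unique(lens[-1])) != 1L || lens[1] != lens[2])
    stop("inconsistent series lengths across pixel rows in ", path)
  t_len <- lens[2] - 2L
  vals <- matrix(as.numeric(unlist(toks[-1])), ncol = lens[2], byrow = TRUE)
  rows <- as.integer(vals[, 1]) + 1L
  cols <- as.integer(vals[, 2]) + 1L
  h <- if (!is.null(hdr$height)) as.integer(hdr$height) else max(rows)
  w <- if (!is.null(hdr$width)) as.integer(hdr$width) else max(cols)
  if (any(rows < 1L | rows > h | cols < 1L | cols > w))
    stop("pixel coordinates outside the declared grid extent")
  data <- array(NA_real_, c(h, w, t_len))
  flat <- matrix(NA_real_, h * w, t_len)
  flat[(cols - 1L) * h + rows, ] <- vals[, -(1:2), drop = FALSE]
  data <- array(flat, c(h, w, t_len))
  tr <- if (!is.null(tr_seconds)) tr_seconds else hdr$tr_seconds
  px <- if (!is.null(pixel_mm)) pixel_mm else hdr$pixel_mm
  if (is.null(tr)) stop("`tr_seconds` not supplied and not recorded in the file")
  if (is.null(px)) px <- 2
  ts_grid(data, mask = mask, tr_seconds = tr, pixel_mm = px,
          meta = list(source = path))
}

#' Write a scalar map to disk
#'
#' Delimited output mirrors the grid format: comment header (extent and map
#' kind), then `row`, `col` (0-based) and `value` at full precision
#' (lossless round trip). `png16` writes a 16-bit grayscale PNG in which
#' `[min, max]` on the mask maps linearly to `[0, 65535]` (off-mask pixels
#' are 0), plus a JSON sidecar `<path>.json` recording the scale.
#'
#' @param map a [scalar_map()].
#' @param path output file path.
#' @param format `"delimited"` or `"png16"`.
#' @export
write_map <- function(map, path, format = c("delimited", "png16")) {
  format <- match.arg(format)
  v <- map$values[map$mask]
  if (any(!is.finite(v)))
    stop("map has non-finite values on mask pixels; refusing to write")
  d <- dim(map$values)
  if (format == "delimited") {
    idx <- which(map$mask)
    rc <- arrayInd(idx, d)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# arealmap map v1",
                 sprintf("# height=%d width=%d kind=%s", d[1], d[2], map$kind),
                 "row\tcol\tvalue"), con)
    writeLines(sprintf("%d\t%d\t%s", rc[, 1] - 1L, rc[, 2] - 1L,
                       fmt17(map$values[idx])), con)
    return(invisible(NULL))
  }
  lo <- min(v); hi <- max(v)
  scaled <- matrix(0L, d[1], d[2])
  if (hi > lo)
    scaled[map$mask] <- as.integer(round((v - lo) / (hi - lo) * 65535))
  write_png16(scaled, path)
  jsonlite::write_json(list(min = lo, max = hi, height = d[1], width = d[2],
                            kind = map$kind),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Read a delimited scalar map written by [write_map()]
#'
#' @param path input file path.
#' @param kind override the map kind recorded in the header.
#' @return A [scalar_map()].
#' @export
read_map <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hlines <- lines[startsWith(lines, "#")]
  hdr <- parse_header_fields(hlines)
  fkind <- sub(".*kind=(\\S+).*", "\\1",
               hlines[grepl("kind=", hlines)][1])
  body <- lines[!startsWith(lines, "#")][-1]
  toks <- strsplit(body, "\t", fixed = TRUE)
  vals <- matrix(as.numeric(unlist(toks)), ncol = 3L, byrow = TRUE)
  h <- as.integer(hdr$height); w <- as.integer(hdr$width)
  m <- matrix(NA_real_, h, w)
  mask <- matrix(FALSE, h, w)
  ij <- cbind(as.integer(vals[, 1]) + 1L, as.integer(vals[, 2]) + 1L)
  m[ij] <- vals[, 3]
  mask[ij] <- TRUE
  scalar_map(m, mask, kind = if (is.null(kind)) fkind else kind)
}

# ---- minimal 16-bit grayscale PNG writer -----------------------------------
# No installed R package writes 16-bit PNG (png::writePNG is 8-bit), so the
# chunks are assembled here: IHDR/IDAT/IEND with CRC32, IDAT deflate via
# memCompress (zlib stream, as PNG requires). png::readPNG decodes 16-bit.

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(c, 1L)) else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  ints <- as.integer(bytes)
  for (b in ints)
    c <- bitwXor(bitwShiftR(c, 8L), crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L])
  bitwXor(c, -1L)
}

u32be <- function(x) {
  # x may exceed .Machine$integer.max range as a double; emit 4 bytes big-endian
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(body)))
}

# ints: integer matrix (rows x cols) with values in [0, 65535]
write_png16 <- function(ints, path) {
  stopifnot(is.matrix(ints), all(ints >= 0L), all(ints <= 65535L))
  h <- nrow(ints); w <- ncol(ints)
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  rowbytes <- lapply(seq_len(h), function(r) {
    v <- ints[r, ]
    as.raw(c(0L, rbind(v %/% 256L, v %% 256L)))
  })
  idat <- memCompress(do.call(c, rowbytes), "gzip")
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(NULL)
}
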