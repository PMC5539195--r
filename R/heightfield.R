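#' Heightfield terrain grids
#'
#' A heightfield is a numeric matrix of per-cell elevations normalised to
#' `[0, 1]` (an 8-bit grey level `g` maps linearly to `g/255`). Pixel
#' intensity corresponds to topographic height, matching the convention of
#' greyscale digital elevation rasters. The matrix is stored in raster order:
#' row 1 is the top image row, and all coordinates in this package are
#' 0-based `(row, col)` with the origin at the top-left cell.
#'
#' @param values numeric matrix of elevations in `[0, 1]`.
#' @return A `heightfield` object (a classed numeric matrix).
#' @export
heightfield <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("heightfield must be at least 1x1", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("heightfield values must be finite", call. = FALSE)
  }
  if (any(values < 0) || any(values > 1)) {
    stop("heightfield values must lie in [0, 1]", call. = FALSE)
  }
  structure(values, class = c("heightfield", class(matrix())))
}

#' @export
print.heightfield <- function(x, ...) {
  cat(sprintf(
    "<heightfield> %d x %d cells, elevation range [%.3f, %.3f]\n",
    nrow(x), ncol(x), min(x), max(x)
  ))
  invisible(x)
}

is_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  magic %in% c("P2", "P5")
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens: magic, width, height, maxval; '#' comments allowed
  tokens <- character(0)
  buf <- character(0)
  in_comment <- FALSE
  while (length(tokens) < 4L) {
    ch <- readBin(con, "raw", 1L)
    if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
    ch <- rawToChar(ch)
    if (in_comment) {
      if (ch == "\n") in_comment <- FALSE
      next
    }
    if (ch == "#") {
      in_comment <- TRUE
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (nchar(paste(buf, collapse = "")) > 0L) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, ch)
    }
  }
  magic <- tokens[1L]
  w <- as.integer(tokens[2L])
  h <- as.integer(tokens[3L])
  maxval <- as.integer(tokens[4L])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file", call. = FALSE)
  if (is.na(w) || is.na(h) || w < 1L || h < 1L) {
    stop("invalid PGM dimensions", call. = FALSE)
  }
  if (magic == "P5") {
    if (maxval > 255L) {
      vals <- readBin(con, "integer", n = w * h, size = 2L, signed = FALSE,
                      endian = "big")
    } else {
      vals <- as.integer(readBin(con, "raw", n = w * h))
    }
  } else {
    rest <- readLines(con, warn = FALSE)
    vals <- as.integer(scan(text = paste(rest, collapse = "\n"),
                            what = integer(), quiet = TRUE))
  }
  if (length(vals) < w * h) stop("truncated PGM pixel data", call. = FALSE)
  list(
    pixels = matrix(vals[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE),
    maxval = maxval
  )
}

write_pgm <- function(pixels, path, maxval = 255L) {
  con <- file(path, "wb")
  on.exit(close(con))
  h <- nrow(pixels)
  w <- ncol(pixels)
  writeBin(charToRaw(sprintf("P5\n%d %d\n%d\n", w, h, maxval)), con)
  flat <- as.integer(t(pixels)) # raster order: row by row
  if (maxval > 255L) {
    writeBin(flat, con, size = 2L, endian = "big")
  } else {
    writeBin(as.raw(flat), con)
  }
  invisible(path)
}

#' Load a heightfield from an 8-bit greyscale raster
#'
#' Reads a PGM (P5 binary or P2 ASCII) or 8-bit greyscale PNG raster and maps
#' grey levels linearly to elevations: `value = grey / 255` exactly.
#' Multi-channel or deeper-than-8-bit rasters are rejected.
#'
#' @param path path to a PGM or PNG file.
#' @return A [heightfield()].
#' @export
load_heightfield <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  if (is_pgm(path)) {
    pgm <- read_pgm(path)
    if (pgm$maxval > 255L) {
      stop("heightfield rasters must be 8-bit (maxval 255)", call. = FALSE)
    }
    return(heightfield(pgm$pixels / 255))
  }
  img <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e) stop("unreadable raster: ", path,
                                           call. = FALSE))
  info <- attr(img, "info")
  if (!is.null(info) && !is.null(info$bit.depth) && info$bit.depth > 8L) {
    stop("heightfield rasters must be 8-bit", call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    stop("heightfield rasters must be single-channel greyscale", call. = FALSE)
  }
  # readPNG returns grey/255 for 8-bit input; re-quantise to exact grey levels
  heightfield(matrix(round(img * 255) / 255, nrow(img), ncol(img)))
}

#' Write a heightfield as an 8-bit PGM raster
#'
#' Inverse of [load_heightfield()]: values are mapped back to grey levels via
#' `round(value * 255)`, so fields that originate from valid 8-bit rasters
#' round-trip exactly.
#'
#' @param hf a [heightfield()] or numeric matrix in `[0, 1]`.
#' @param path output path (`.pgm`).
#' @return `path`, invisibly.
#' @export
write_heightfield <- function(hf, path) {
  hf <- heightfield(unclass(hf))
  write_pgm(round(unclass(hf) * 255), path, maxval = 255L)
}

#' Generate a synthetic ridge terrain
#'
#' Builds a heightfield as a clipped sum of anisotropic Gaussian ridges, a
#' stand-in for satellite-derived elevation rasters that keeps every stage of
#' the pipeline testable offline. The construction is referentially
#' transparent: the same ridge specification and seed always produce a
#' bit-identical field.
#'
#' @param width,height_px grid dimensions in cells (columns, rows).
#' @param ridges a data frame (or list coercible to one) with columns
#'   `center_row`, `center_col` (0-based), `orientation` (degrees, the ridge
#'   long axis), `amplitude` (peak height in `[0, 1]`), `sigma_along`,
#'   `sigma_across` (Gaussian spreads in cells, along/across the axis).
#'   An empty specification yields a flat zero field.
#' @param seed integer seed for the optional additive noise.
#' @param noise_sd standard deviation of optional Gaussian pixel noise
#'   (default 0 = none).
#' @return A [heightfield()].
#' @export
synth_heightfield <- function(width, height_px, ridges = NULL, seed = 1L,
                              noise_sd = 0) {
  vals <- matrix(0, nrow = height_px, ncol = width)
  if (!is.null(ridges) && NROW(ridges) > 0L) {
    ridges <- tibble::as_tibble(ridges)
    if (any(ridges$amplitude < 0 | ridges$amplitude > 1)) {
      stop("ridge amplitudes must lie in [0, 1]", call. = FALSE)
    }
    rr <- matrix(rep(0:(height_px - 1L), times = width), nrow = height_px)
    cc <- matrix(rep(0:(width - 1L), each = height_px), nrow = height_px)
    for (i in seq_len(nrow(ridges))) {
      g <- ridges[i, ]
      th <- g$orientation * pi / 180
      dr <- rr - g$center_row
      dc <- cc - g$center_col
      # rotate into ridge frame: u along the axis, v across it
      u <- dc * cos(th) + dr * sin(th)
      v <- -dc * sin(th) + dr * cos(th)
      vals <- vals + g$amplitude *
        exp(-0.5 * (u / g$sigma_along)^2 - 0.5 * (v / g$sigma_across)^2)
    }
  }
  if (noise_sd > 0) {
    vals <- vals + local_rnorm(length(vals), sd = noise_sd, seed = seed)
  }
  heightfield(pmin(pmax(vals, 0), 1))
}

# draw from R's RNG without disturbing the caller's RNG state
local_rnorm <- function(n, sd, seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}
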