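#' Read a region-site table
#'
#' Sites are the nutrient attractant locations standing in for regional
#' centres. The CSV must have header `region_id,name,row,col` with 0-based
#' cell coordinates (origin top-left, matching raster order).
#'
#' @param path CSV file path.
#' @return A tibble with columns `region_id` (integer), `name` (character),
#'   `row`, `col` (integer), one row per site, input order preserved. An
#'   empty file (header only) yields an empty tibble.
#' @export
load_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("region_id", "name", "row", "col")
  if (!all(required %in% names(df))) {
    stop("sites CSV must have columns region_id,name,row,col", call. = FALSE)
  }
  sites <- tibble::tibble(
    region_id = as.integer(df$region_id),
    name = as.character(df$name),
    row = as.integer(df$row),
    col = as.integer(df$col)
  )
  validate_sites(sites)
  sites
}

#' Write a region-site table
#' @param sites tibble as returned by [load_sites()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.csv(sites[, c("region_id", "name", "row", "col")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_sites <- function(sites) {
  if (nrow(sites) == 0L) return(invisible(sites))
  if (anyNA(sites$region_id) || anyNA(sites$row) || anyNA(sites$col)) {
    stop("sites contain missing values", call. = FALSE)
  }
  if (anyDuplicated(sites$region_id)) {
    dup <- sites$region_id[duplicated(sites$region_id)]
    stop("duplicate region_id in sites: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  invisible(sites)
}

#' Derive a habitability mask from a raster or a heightfield
#'
#' Two entry points for the arena mask dialect: in a mask raster any non-zero
#' grey is habitable (white = habitable); alternatively, habitability can be
#' derived from a heightfield as the cells strictly below an elevation
#' cutoff.
#'
#' @param path path to an 8-bit greyscale raster (PGM/PNG).
#' @return A logical matrix (`TRUE` = habitable).
#' @export
mask_from_raster <- function(path) {
  hf <- load_heightfield(path)
  unclass(hf) > 0
}

#' @rdname mask_from_raster
#' @param hf a [heightfield()].
#' @param cutoff elevation in `[0, 1]`; cells with height `< cutoff` are
#'   habitable.
#' @export
mask_from_height <- function(hf, cutoff) {
  unclass(hf) < cutoff
}

#' Assemble a simulation arena
#'
#' An arena bundles the habitability mask, the region sites, and (optionally)
#' a terrain heightfield. Absence of a heightfield is the "no-height"
#' condition. All invariants are validated here: dimensions must agree, every
#' site must lie on a habitable cell inside the grid, and region ids must be
#' unique.
#'
#' @param mask logical matrix (`TRUE` = habitable), or a raster path accepted
#'   by [mask_from_raster()].
#' @param sites site tibble ([load_sites()]) or a data frame with columns
#'   `region_id`, `name`, `row`, `col` (0-based coordinates).
#' @param heightfield optional [heightfield()] with the same dimensions as
#'   `mask`.
#' @return An object of class `arena`.
#' @export
make_arena <- function(mask, sites, heightfield = NULL) {
  if (is.character(mask)) mask <- mask_from_raster(mask)
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix", call. = FALSE)
  }
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) > 0 && !all(c("region_id", "name", "row", "col") %in%
                              names(sites))) {
    stop("sites need columns region_id, name, row, col", call. = FALSE)
  }
  if (nrow(sites) == 0L) {
    sites <- tibble::tibble(region_id = integer(), name = character(),
                            row = integer(), col = integer())
  }
  validate_sites(sites)
  if (!is.null(heightfield)) {
    heightfield <- heightfield(unclass(heightfield))
    if (nrow(heightfield) != nrow(mask) || ncol(heightfield) != ncol(mask)) {
      stop("mask and heightfield dimensions differ", call. = FALSE)
    }
  }
  if (nrow(sites) > 0L) {
    inside <- sites$row >= 0 & sites$row < nrow(mask) &
      sites$col >= 0 & sites$col < ncol(mask)
    if (!all(inside)) {
      stop("sites outside grid: region_id ",
           paste(sites$region_id[!inside], collapse = ", "), call. = FALSE)
    }
    habitable <- mask[cbind(sites$row + 1L, sites$col + 1L)]
    if (!all(habitable)) {
      stop("sites on non-habitable cells: region_id ",
           paste(sites$region_id[!habitable], collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(mask = mask, sites = sites, heightfield = heightfield),
    class = "arena"
  )
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf(
    "<arena> %d x %d cells, %d habitable, %d sites, %s\n",
    nrow(x$mask), ncol(x$mask), sum(x$mask), nrow(x$sites),
    if (is.null(x$heightfield)) "no-height condition" else "with heightfield"
  ))
  invisible(x)
}

arena_dims <- function(arena) c(nrow(arena$mask), ncol(arena$mask))
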