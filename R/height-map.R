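#' Raster height map
#'
#' A `height_map` is the package's stand-in for a 3D photogrammetric surface
#' reconstruction: a regular 2D grid of elevations (mm) with a known,
#' isotropic pixel spacing (mm/pixel). Coordinates follow image convention:
#' x to the right, y downward, origin at the grid corner; the centre of cell
#' `[row i, col j]` sits at `((j - 0.5) * spacing, (i - 0.5) * spacing)`.
#'
#' @param elevations Numeric matrix of elevations in mm. Rows index y,
#'   columns index x. `NA` entries are treated as nodata and excluded from
#'   every integral.
#' @param pixel_spacing Pixel spacing in mm/pixel; must be a single positive
#'   number.
#' @returns An object of class `height_map`: a list with elements
#'   `elevations` and `pixel_spacing`.
#' @examples
#' hm <- height_map(matrix(0, 8, 8), pixel_spacing = 0.5)
#' dim(hm$elevations)
#' @export
height_map <- function(elevations, pixel_spacing) {
  if (!is.matrix(elevations) || !is.numeric(elevations)) {
    abort("`elevations` must be a numeric matrix.")
  }
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      !is.finite(pixel_spacing) || pixel_spacing <= 0) {
    abort("`pixel_spacing` must be a single positive number (mm/pixel).")
  }
  structure(
    list(elevations = elevations, pixel_spacing = as.numeric(pixel_spacing)),
    class = "height_map"
  )
}

#' @export
print.height_map <- function(x, ...) {
  d <- dim(x$elevations)
  cat(sprintf(
    "<height_map> %d x %d cells, %.4g mm/pixel (%.3g x %.3g mm), %d nodata\n",
    d[1], d[2], x$pixel_spacing,
    d[2] * x$pixel_spacing, d[1] * x$pixel_spacing,
    sum(is.na(x$elevations))
  ))
  invisible(x)
}

#' @export
dim.height_map <- function(x) dim(x$elevations)

# x/y coordinates (mm) of all cell centres, as vectors aligned with
# as.vector(elevations) (column-major).
cell_centers <- function(map) {
  d <- dim(map$elevations)
  s <- map$pixel_spacing
  list(
    x = rep((seq_len(d[2]) - 0.5) * s, each = d[1]),
    y = rep((seq_len(d[1]) - 0.5) * s, times = d[2])
  )
}

#' Read and write height maps as ASCII grid rasters
#'
#' Plain-text ESRI ASCII-grid dialect: a header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' elevations in mm, first row = top of the image (smallest y).
#'
#' @param map A [height_map()].
#' @param path File path.
#' @returns `write_height_map()` returns `path` invisibly;
#'   `read_height_map()` returns a [height_map()].
#' @export
write_height_map <- function(map, path) {
  stopifnot(inherits(map, "height_map"))
  d <- dim(map$elevations)
  nodata <- -9999
  z <- map$elevations
  z[is.na(z)] <- nodata
  header <- c(
    paste("ncols", d[2]),
    paste("nrows", d[1]),
    "xllcorner 0",
    "yllcorner 0",
    paste("cellsize", format(map$pixel_spacing, digits = 15)),
    paste("NODATA_value", nodata)
  )
  rows <- apply(z, 1L, function(r) paste(format(r, digits = 15, trim = TRUE),
                                         collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  need <- c("ncols", "nrows", "cellsize", "nodata_value")
  if (!all(need %in% keys)) {
    abort(paste0("Malformed ASCII grid header in '", path, "'."))
  }
  h <- setNames(vals, keys)
  z <- matrix(
    scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE),
    nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE
  )
  z[z == h[["nodata_value"]]] <- NA_real_
  height_map(z, pixel_spacing = h[["cellsize"]])
}

#' Plot a height map
#'
#' @param object A [height_map()].
#' @param ... Unused.
#' @returns A ggplot raster of elevations with mm axes.
#' @exportS3Method ggplot2::autoplot
autoplot.height_map <- function(object, ...) {
  cc <- cell_centers(object)
  df <- tibble::tibble(x = cc$x, y = cc$y,
                       elevation_mm = as.vector(object$elevations))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$elevation_mm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = "elevation (mm)") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}
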