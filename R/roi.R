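#' Region-of-interest polygon
#'
#' An ROI is a simple (non-self-intersecting) closed polygon in the height
#' map's mm coordinate system, drawn either around the lesion or on adjacent
#' normal skin (the background region used for the reference-plane fit).
#' Vertices are stored once; the closing edge back to the first vertex is
#' implicit.
#'
#' @param x,y Numeric vertex coordinates in mm (at least 3 vertices).
#' @param label `"lesion"` or `"background"`.
#' @returns A tibble of class `roi_polygon` with columns `x_mm`, `y_mm` and
#'   a `label` attribute.
#' @examples
#' roi_polygon(c(0, 4, 4, 0), c(0, 0, 4, 4), label = "background")
#' @export
roi_polygon <- function(x, y, label = c("lesion", "background")) {
  label <- match.arg(label)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("An ROI polygon needs at least 3 vertices.")
  if (anyNA(x) || anyNA(y)) abort("ROI vertices must not contain NA.")
  # drop an explicitly repeated closing vertex
  n <- length(x)
  if (n > 3L && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  if (abs(polygon_area(x, y)) <= 0) abort("ROI polygon has zero area.")
  if (!polygon_is_simple(x, y)) abort("ROI polygon is self-intersecting.")
  out <- tibble::new_tibble(
    list(x_mm = as.numeric(x), y_mm = as.numeric(y)),
    nrow = length(x), class = "roi_polygon"
  )
  attr(out, "label") <- label
  out
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon: %s> %d vertices, area %.4g mm^2\n",
              attr(x, "label") %||% "?", nrow(x),
              polygon_area(x$x_mm, x$y_mm)))
  NextMethod()
}

#' Regular-polygon approximation to an ellipse
#'
#' Convenience constructor for circular / elliptical ROIs: `n` vertices on an
#' axis-aligned ellipse (optionally rotated), including the points on the
#' major axis.
#'
#' @param center Numeric length-2 centre (mm).
#' @param a,b Semi-axes in mm (`b` defaults to `a`, i.e. a circle).
#' @param n Number of vertices.
#' @param angle Rotation of the `a` axis, radians.
#' @inheritParams roi_polygon
#' @returns A [roi_polygon()].
#' @export
ellipse_roi <- function(center, a, b = a, n = 256L, angle = 0,
                        label = "lesion") {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x0 <- a * cos(th); y0 <- b * sin(th)
  roi_polygon(
    center[1] + x0 * cos(angle) - y0 * sin(angle),
    center[2] + x0 * sin(angle) + y0 * cos(angle),
    label = label
  )
}

# Shoelace signed area; exported consumers use abs().
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# Even-odd (crossing number) point-in-polygon test, vectorised over points.
# Points exactly on a horizontal edge resolve via the half-open rule; this is
# the deterministic cell-membership rule used for all integrals.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

# Proper segment intersection test for two batches of segments (vectorised
# over the first). Touching at endpoints does not count.
segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  o1 <- o(ax, ay, bx, by, cx, cy)
  o2 <- o(ax, ay, bx, by, dx, dy)
  o3 <- o(cx, cy, dx, dy, ax, ay)
  o4 <- o(cx, cy, dx, dy, bx, by)
  (o1 * o2 < 0) & (o3 * o4 < 0)
}

polygon_is_simple <- function(x, y) {
  n <- length(x)
  if (n <= 3L) return(TRUE)
  nx <- c(x[-1L], x[1L]); ny <- c(y[-1L], y[1L])
  for (i in seq_len(n - 2L)) {
    # skip adjacent edges (shared endpoint)
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]
    if (!length(js)) next
    if (any(segments_cross(x[i], y[i], nx[i], ny[i],
                           x[js], y[js], nx[js], ny[js]))) {
      return(FALSE)
    }
  }
  TRUE
}

# TRUE if two simple polygons overlap (vertex containment either way, or any
# pair of edges properly crossing).
polygons_overlap <- function(p1, p2) {
  if (any(point_in_polygon(p1$x_mm, p1$y_mm, p2$x_mm, p2$y_mm))) return(TRUE)
  if (any(point_in_polygon(p2$x_mm, p2$y_mm, p1$x_mm, p1$y_mm))) return(TRUE)
  x1 <- p1$x_mm; y1 <- p1$y_mm; x2 <- p2$x_mm; y2 <- p2$y_mm
  nx1 <- c(x1[-1L], x1[1L]); ny1 <- c(y1[-1L], y1[1L])
  nx2 <- c(x2[-1L], x2[1L]); ny2 <- c(y2[-1L], y2[1L])
  for (i in seq_along(x1)) {
    if (any(segments_cross(x1[i], y1[i], nx1[i], ny1[i], x2, y2, nx2, ny2))) {
      return(TRUE)
    }
  }
  FALSE
}

# Logical mask (same shape as map$elevations) of cells whose centre lies
# inside the ROI. Nodata cells are left in the mask here; integrals drop
# them explicitly so the skipped count can be reported.
roi_cell_mask <- function(map, roi) {
  stopifnot(inherits(map, "height_map"), inherits(roi, "roi_polygon"))
  cc <- cell_centers(map)
  matrix(point_in_polygon(cc$x, cc$y, roi$x_mm, roi$y_mm),
         nrow = nrow(map$elevations))
}

#' Read and write ROI polygons as CSV vertex lists
#'
#' Columns `x_mm`, `y_mm`; one vertex per row, polygon implicitly closed.
#'
#' @param roi A [roi_polygon()].
#' @param path File path.
#' @param label Label to attach on read.
#' @returns `write_roi()` returns `path` invisibly; `read_roi()` an
#'   [roi_polygon()].
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi_polygon"))
  utils::write.csv(as.data.frame(roi), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path, label = "lesion") {
  df <- utils::read.csv(path)
  names(df) <- tolower(names(df))
  if (!all(c("x_mm", "y_mm") %in% names(df))) {
    abort(paste0("ROI file '", path, "' must have columns x_mm, y_mm."))
  }
  roi_polygon(df$x_mm, df$y_mm, label = label)
}
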