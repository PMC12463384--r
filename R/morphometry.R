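#' Fit the reference skin plane
#'
#' Ordinary least-squares plane \eqn{z = a x + b y + c} through the centres
#' of all grid cells inside the background (normal skin) ROI. Every signed
#' elevation, volume and height downstream is measured relative to this
#' plane, the package's stand-in for the "surface plane" a photogrammetric
#' system references its cut-and-fill volumes to.
#'
#' @param map A [height_map()].
#' @param background A [roi_polygon()] drawn on normal skin.
#' @returns A list of class `reference_plane`: `a`, `b`, `c`,
#'   `rms_residual` (mm), `n_points_fit`.
#' @export
fit_reference_plane <- function(map, background) {
  stopifnot(inherits(map, "height_map"))
  mask <- roi_cell_mask(map, background)
  z <- map$elevations[mask]
  cc <- cell_centers(map)
  x <- cc$x[mask]; y <- cc$y[mask]
  keep <- !is.na(z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  if (length(z) < 3L) {
    abort("Background ROI contains fewer than 3 usable cells; cannot fit a plane.")
  }
  if (qr(cbind(x - mean(x), y - mean(y)))$rank < 2L) {
    abort("Background cells are collinear; plane fit is degenerate.")
  }
  fit <- lm(z ~ x + y)
  res <- fit$residuals
  structure(
    list(a = unname(coef(fit)[["x"]]), b = unname(coef(fit)[["y"]]),
         c = unname(coef(fit)[["(Intercept)"]]),
         rms_residual = sqrt(mean(res^2)), n_points_fit = length(z)),
    class = "reference_plane"
  )
}

#' @export
print.reference_plane <- function(x, ...) {
  cat(sprintf(
    "<reference_plane> z = %.6g x + %.6g y + %.6g  (rms %.4g mm, n = %d)\n",
    x$a, x$b, x$c, x$rms_residual, x$n_points_fit))
  invisible(x)
}

plane_at <- function(plane, x, y) plane$a * x + plane$b * y + plane$c

# Signed residuals (elevation - plane) over in-ROI cells, NA-dropped, with
# the skipped-nodata count attached.
roi_residuals <- function(map, roi, plane) {
  mask <- roi_cell_mask(map, roi)
  if (!any(mask)) abort("ROI contains no grid-cell centres.")
  cc <- cell_centers(map)
  z <- map$elevations[mask]
  res <- z - plane_at(plane, cc$x[mask], cc$y[mask])
  n_nodata <- sum(is.na(res))
  structure(res[!is.na(res)], n_nodata = n_nodata)
}

#' Cut-and-fill volumes relative to the reference plane
#'
#' Per grid cell inside the lesion ROI, the signed residual
#' (elevation minus plane) times the cell area is accumulated into positive
#' volume (material above the plane) and negative volume (below, e.g.
#' ulceration). Absolute volume — 3DAbsVol, the primary size measure — is
#' the positive volume plus the magnitude of the negative volume; net volume
#' is their signed sum.
#'
#' @param map A [height_map()].
#' @param lesion Lesion [roi_polygon()].
#' @param plane A [fit_reference_plane()] result.
#' @returns One-row tibble: `positive_volume_mm3`, `negative_volume_mm3`
#'   (<= 0), `net_volume_mm3`, `absolute_volume_mm3`, `n_cells`,
#'   `n_nodata_skipped`.
#' @export
compute_volumes <- function(map, lesion, plane) {
  res <- roi_residuals(map, lesion, plane)
  if (length(res) == 0L) abort("All in-ROI cells are nodata; no volume defined.")
  cell_area <- map$pixel_spacing^2
  pos <- sum(pmax(res, 0)) * cell_area
  neg <- sum(pmin(res, 0)) * cell_area
  tibble::tibble(
    positive_volume_mm3 = pos,
    negative_volume_mm3 = neg,
    net_volume_mm3 = pos + neg,
    absolute_volume_mm3 = pos + abs(neg),
    n_cells = length(res),
    n_nodata_skipped = attr(res, "n_nodata")
  )
}

#' Lesion heights
#'
#' `max_height_mm` is the largest in-ROI residual above the plane (floored
#' at 0, so a purely ulcerated lesion reports 0 rather than a negative
#' height). `average_height_mm` — 3DAvHt, the depth surrogate — is absolute
#' volume divided by lesion area.
#'
#' @inheritParams compute_volumes
#' @param absolute_volume_mm3 Absolute volume of the lesion (mm^3).
#' @param surface_area_mm2 Projected lesion ROI area (mm^2); must be > 0.
#' @returns One-row tibble with `max_height_mm` and `average_height_mm`.
#' @export
compute_heights <- function(map, lesion, plane, absolute_volume_mm3,
                            surface_area_mm2) {
  if (surface_area_mm2 <= 0) abort("`surface_area_mm2` must be > 0.")
  res <- roi_residuals(map, lesion, plane)
  tibble::tibble(
    max_height_mm = max(c(res, 0)),
    average_height_mm = absolute_volume_mm3 / surface_area_mm2
  )
}

#' Major and perpendicular Feret diameters of an ROI
#'
#' The major diameter is the maximum Feret diameter: the largest distance
#' between any two polygon vertices (attained on the convex hull). The
#' perpendicular diameter is the extent of the polygon projected onto the
#' axis orthogonal to the major axis.
#'
#' @param lesion A [roi_polygon()].
#' @returns One-row tibble: `major_diameter_mm`, `perpendicular_diameter_mm`.
#' @export
compute_diameters <- function(lesion) {
  stopifnot(inherits(lesion, "roi_polygon"))
  x <- lesion$x_mm; y <- lesion$y_mm
  hull <- grDevices::chull(x, y)
  if (length(hull) < 3L) abort("Degenerate (collinear) polygon; diameters undefined.")
  hx <- x[hull]; hy <- y[hull]
  d2 <- outer(hx, hx, `-`)^2 + outer(hy, hy, `-`)^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1L, ]
  major <- sqrt(d2[ij[1L], ij[2L]])
  u <- c(hx[ij[2L]] - hx[ij[1L]], hy[ij[2L]] - hy[ij[1L]]) / major
  perp_proj <- -u[2L] * x + u[1L] * y
  tibble::tibble(
    major_diameter_mm = major,
    perpendicular_diameter_mm = max(perp_proj) - min(perp_proj)
  )
}

#' Surface roughness (Rq)
#'
#' Root-mean-square of the plane residuals over in-ROI cells — the standard
#' surface-metrology Rq parameter, used here as the lesion "roughness".
#'
#' @inheritParams compute_volumes
#' @returns Roughness in mm (single number).
#' @export
compute_roughness <- function(map, lesion, plane) {
  res <- roi_residuals(map, lesion, plane)
  if (length(res) == 0L) abort("All in-ROI cells are nodata; roughness undefined.")
  sqrt(mean(res^2))
}

#' Full morphometry report for one lesion
#'
#' Fits the reference plane to the background ROI, then computes the eight
#' per-lesion parameters a photogrammetric report window shows: projected
#' surface area, major and perpendicular diameters, positive/negative/net
#' volume, absolute volume (3DAbsVol), maximum and average height (3DAvHt),
#' and roughness.
#'
#' @param map A [height_map()].
#' @param lesion,background Lesion and background [roi_polygon()]s; must not
#'   overlap.
#' @returns A one-row tibble (`morphometry_report`) with the ten parameter
#'   columns plus bookkeeping (`n_cells`, `n_nodata_skipped`,
#'   `plane_rms_mm`); the fitted plane is attached as attribute `"plane"`.
#' @examples
#' sc <- make_lesion_scene(
#'   lesion_shape("spherical_cap", radius_mm = 1.5, height_mm = 0.5),
#'   skin_params(grid_size = 96, pixel_spacing = 0.06, noise_sd = 0)
#' )
#' analyze_roi(sc$map, sc$lesion_roi, sc$background_roi)
#' @export
analyze_roi <- function(map, lesion, background) {
  stopifnot(inherits(lesion, "roi_polygon"),
            inherits(background, "roi_polygon"))
  if (polygons_overlap(lesion, background)) {
    abort("Lesion and background ROIs overlap.")
  }
  plane <- fit_reference_plane(map, background)
  area <- abs(polygon_area(lesion$x_mm, lesion$y_mm))
  vols <- compute_volumes(map, lesion, plane)
  hts <- compute_heights(map, lesion, plane,
                         absolute_volume_mm3 = vols$absolute_volume_mm3,
                         surface_area_mm2 = area)
  dia <- compute_diameters(lesion)
  out <- dplyr::bind_cols(
    tibble::tibble(surface_area_mm2 = area),
    dia,
    vols[, c("positive_volume_mm3", "negative_volume_mm3",
             "net_volume_mm3", "absolute_volume_mm3")],
    hts,
    tibble::tibble(
      roughness_mm = compute_roughness(map, lesion, plane),
      n_cells = vols$n_cells,
      n_nodata_skipped = vols$n_nodata_skipped,
      plane_rms_mm = plane$rms_residual
    )
  )
  attr(out, "plane") <- plane
  class(out) <- c("morphometry_report", class(out))
  out
}
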