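#' Synthetic skin surface parameters
#'
#' Describes the "normal skin" background on which synthetic lesions and
#' phantoms are placed: a (possibly tilted) plane plus i.i.d. Gaussian
#' micro-roughness per pixel. Real skin texture is spatially correlated;
#' this deliberately minimal model is enough to exercise the reference-plane
#' fit and the volume integrals.
#'
#' @param grid_size Pixels per side (square grid).
#' @param pixel_spacing mm per pixel; must be > 0.
#' @param tilt Length-2 plane slope (mm per mm) in x and y.
#' @param noise_sd Micro-roughness standard deviation in mm (>= 0).
#' @param seed Integer seed; identical seeds reproduce identical surfaces.
#' @returns A list of class `skin_params`.
#' @export
skin_params <- function(grid_size = 128L, pixel_spacing = 0.05,
                        tilt = c(0, 0), noise_sd = 0.02, seed = 1L) {
  if (pixel_spacing <= 0) abort("`pixel_spacing` must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (length(tilt) != 2L) abort("`tilt` must have two components.")
  structure(
    list(grid_size = as.integer(grid_size),
         pixel_spacing = as.numeric(pixel_spacing),
         tilt = as.numeric(tilt), noise_sd = as.numeric(noise_sd),
         seed = as.integer(seed)),
    class = "skin_params"
  )
}

#' Synthetic lesion shape
#'
#' Parametric lesion geometries added to the skin surface: a spherical cap,
#' an ellipsoidal cap, or a spherical cap with a central crater-like
#' ulceration that dips below the skin plane (raised edges with central
#' ulceration are a classic BCC presentation).
#'
#' @param kind `"spherical_cap"`, `"ellipsoidal_cap"` or `"cap_with_ulcer"`.
#' @param radius_mm Base (footprint) radius in mm; for `"ellipsoidal_cap"` a
#'   length-2 vector of semi-axes is accepted.
#' @param height_mm Peak height of the cap above the plane (>= 0).
#' @param ulcer_depth_mm Depth of the central ulcer below the skin plane
#'   (>= 0; only used by `"cap_with_ulcer"`, where the crater footprint is
#'   half the lesion radius).
#' @param center Lesion centre in mm, or `NULL` for the grid centre.
#' @returns A list of class `lesion_shape`.
#' @export
lesion_shape <- function(kind = c("spherical_cap", "ellipsoidal_cap",
                                  "cap_with_ulcer"),
                         radius_mm, height_mm, ulcer_depth_mm = 0,
                         center = NULL) {
  kind <- match.arg(kind)
  if (any(radius_mm < 0)) abort("`radius_mm` must be >= 0.")
  if (height_mm < 0) abort("`height_mm` must be >= 0.")
  if (ulcer_depth_mm < 0) abort("`ulcer_depth_mm` must be >= 0.")
  if (kind != "ellipsoidal_cap" && length(radius_mm) != 1L) {
    abort("`radius_mm` must be scalar unless kind = 'ellipsoidal_cap'.")
  }
  structure(
    list(kind = kind, radius_mm = as.numeric(radius_mm),
         height_mm = as.numeric(height_mm),
         ulcer_depth_mm = as.numeric(ulcer_depth_mm), center = center),
    class = "lesion_shape"
  )
}

# Radial elevation profile of a spherical cap with base radius a and peak
# height h: z(d) = sqrt(R^2 - d^2) - (R - h), R = (a^2 + h^2) / (2h).
cap_profile <- function(d, a, h) {
  if (a <= 0 || h <= 0) return(rep(0, length(d)))
  R <- (a^2 + h^2) / (2 * h)
  z <- sqrt(pmax(R^2 - d^2, 0)) - (R - h)
  ifelse(d <= a, pmax(z, 0), 0)
}

# Radial profile of the full lesion (cap, possibly with central crater).
# Returns elevation relative to the skin plane at radial distance d.
lesion_profile <- function(shape) {
  a <- shape$radius_mm[1L]
  h <- shape$height_mm
  if (shape$kind != "cap_with_ulcer" || shape$ulcer_depth_mm <= 0) {
    return(function(d) cap_profile(d, a, h))
  }
  ru <- a / 2
  z_rim <- cap_profile(ru, a, h)
  hc <- z_rim + shape$ulcer_depth_mm  # crater height from rim to floor
  function(d) {
    z <- cap_profile(d, a, h)
    inner <- d <= ru
    # crater: inverted cap from the rim circle down to -ulcer_depth at centre
    z[inner] <- z_rim - cap_profile(d[inner], ru, hc)
    z
  }
}

# Positive and negative volumes of a radially symmetric profile, by adaptive
# 1D quadrature of 2*pi*d*z(d); exact up to quadrature tolerance, and
# independent of any grid. Used as the analytic ground truth.
radial_volumes <- function(profile, r_max) {
  if (r_max <= 0) return(list(positive = 0, negative = 0))
  grid <- seq(0, r_max, length.out = 2048L)
  z <- profile(grid)
  idx <- which(z[-length(z)] * z[-1L] < 0)  # strict sign changes
  roots <- vapply(idx, function(i) {
    uniroot(profile, lower = grid[i], upper = grid[i + 1L], tol = 1e-12)$root
  }, 0)
  cuts <- sort(unique(c(0, roots, r_max)))
  pos <- 0; neg <- 0
  for (k in seq_len(length(cuts) - 1L)) {
    v <- integrate(function(d) 2 * pi * d * profile(d),
                   lower = cuts[k], upper = cuts[k + 1L],
                   rel.tol = 1e-10, subdivisions = 400L)$value
    if (v >= 0) pos <- pos + v else neg <- neg + v
  }
  list(positive = pos, negative = neg)
}

# Evaluate the skin plane (tilt only; noise added separately) and add a
# lesion shape, returning the elevation matrix.
build_surface <- function(skin, shape = NULL, center = NULL) {
  n <- skin$grid_size
  s <- skin$pixel_spacing
  xs <- (seq_len(n) - 0.5) * s
  ys <- (seq_len(n) - 0.5) * s
  z <- outer(ys, xs, function(y, x) skin$tilt[1] * x + skin$tilt[2] * y)
  if (skin$noise_sd > 0) {
    z <- z + withr::with_seed(skin$seed,
                              matrix(rnorm(n * n, 0, skin$noise_sd), n, n))
  }
  if (!is.null(shape)) {
    ctr <- center %||% shape$center %||% rep(n * s / 2, 2L)
    if (shape$kind == "ellipsoidal_cap") {
      a <- shape$radius_mm[1L]
      b <- if (length(shape$radius_mm) > 1L) shape$radius_mm[2L] else a
      h <- shape$height_mm
      # half-ellipsoid: z = h * sqrt(1 - u^2), u = ellipse-normalised radius
      u2 <- outer((ys - ctr[2])^2 / b^2, (xs - ctr[1])^2 / a^2, `+`)
      z <- z + ifelse(u2 <= 1, h * sqrt(pmax(1 - u2, 0)), 0)
      extent <- c(a, b)
    } else {
      prof <- lesion_profile(shape)
      d <- sqrt(outer((ys - ctr[2])^2, (xs - ctr[1])^2, `+`))
      z <- z + matrix(prof(as.vector(d)), n, n)
      extent <- rep(shape$radius_mm[1L], 2L)
    }
    if (ctr[1] - extent[1] < 0 || ctr[1] + extent[1] > n * s ||
        ctr[2] - extent[2] < 0 || ctr[2] + extent[2] > n * s) {
      abort(sprintf(
        "Lesion cap (centre %.3g, %.3g mm; extent %.3g x %.3g mm) does not fit inside the %.3g mm grid.",
        ctr[1], ctr[2], extent[1], extent[2], n * s))
    }
  }
  z
}

# Analytic truth for a lesion shape: positive/negative/net/absolute volume,
# max height, footprint area and average height (absolute / footprint).
shape_truth <- function(shape) {
  if (shape$kind == "ellipsoidal_cap") {
    a <- shape$radius_mm[1L]
    b <- if (length(shape$radius_mm) > 1L) shape$radius_mm[2L] else a
    pos <- 2 / 3 * pi * a * b * shape$height_mm
    neg <- 0
    area <- pi * a * b
    maxh <- shape$height_mm
  } else {
    a <- shape$radius_mm[1L]
    v <- radial_volumes(lesion_profile(shape), a)
    pos <- v$positive; neg <- v$negative
    area <- pi * a^2
    maxh <- if (shape$kind == "cap_with_ulcer" && shape$ulcer_depth_mm > 0) {
      cap_profile(a / 2, a, shape$height_mm)  # rim is the highest point
    } else {
      shape$height_mm
    }
  }
  absv <- pos + abs(neg)
  tibble::tibble(
    positive_volume_mm3 = pos, negative_volume_mm3 = neg,
    net_volume_mm3 = pos + neg, absolute_volume_mm3 = absv,
    max_height_mm = maxh, surface_area_mm2 = area,
    average_height_mm = if (area > 0) absv / area else 0
  )
}

#' Generate a hemispherical calibration phantom height map
#'
#' Emulates photographing an epoxy half-sphere bead stuck on a flat board:
#' the returned grid is the skin/board plane plus a spherical cap, and the
#' true volume is the analytic cap volume (e.g. \eqn{2/3 \pi r^3} for a
#' hemisphere), the quantity a bead of known mass and density provides.
#'
#' @param shape A [lesion_shape()]; `radius_mm = height_mm` gives a
#'   hemisphere.
#' @param skin A [skin_params()]; `noise_sd` may be 0 for an ideal phantom.
#' @returns A list with `map` ([height_map()]) and `true_volume_mm3`.
#' @examples
#' ph <- make_phantom_heightmap(
#'   lesion_shape("spherical_cap", radius_mm = 2, height_mm = 2),
#'   skin_params(grid_size = 64, pixel_spacing = 0.1, noise_sd = 0)
#' )
#' ph$true_volume_mm3  # (2/3) * pi * 8
#' @export
make_phantom_heightmap <- function(shape, skin) {
  stopifnot(inherits(shape, "lesion_shape"), inherits(skin, "skin_params"))
  z <- build_surface(skin, shape)
  truth <- shape_truth(shape)
  list(
    map = height_map(z, pixel_spacing = skin$pixel_spacing),
    true_volume_mm3 = truth$absolute_volume_mm3
  )
}

#' Generate a full synthetic lesion scene
#'
#' A height map containing one lesion on noisy (optionally tilted) skin,
#' together with a lesion ROI drawn around the lesion footprint, a
#' background ROI on clear skin, and the analytic ground-truth morphometry
#' of the injected shape.
#'
#' The lesion ROI is a polygonised circle/ellipse `roi_margin` times the
#' footprint, mimicking an investigator outlining just outside the visible
#' border; ground-truth `average_height_mm` divides by the analytic
#' footprint area, not the (slightly larger) ROI area.
#'
#' @inheritParams make_phantom_heightmap
#' @param roi_margin Lesion ROI radius as a multiple of the footprint
#'   radius.
#' @param background_roi Optional [roi_polygon()] to use as background;
#'   default is a rectangle along the top edge of the grid. Must not overlap
#'   the lesion ROI.
#' @returns A list with `map`, `lesion_roi`, `background_roi` and `truth`
#'   (one-row tibble of analytic morphometry).
#' @export
make_lesion_scene <- function(shape, skin, roi_margin = 1.1,
                              background_roi = NULL) {
  stopifnot(inherits(shape, "lesion_shape"), inherits(skin, "skin_params"))
  n <- skin$grid_size; s <- skin$pixel_spacing; w <- n * s
  ctr <- shape$center %||% c(w / 2, w * 0.58)
  a <- shape$radius_mm[1L]
  b <- if (shape$kind == "ellipsoidal_cap" && length(shape$radius_mm) > 1L) {
    shape$radius_mm[2L]
  } else {
    a
  }
  z <- build_surface(skin, shape, center = ctr)
  lesion_roi <- ellipse_roi(ctr, a * roi_margin, b * roi_margin,
                            label = "lesion")
  if (is.null(background_roi)) {
    background_roi <- roi_polygon(
      x = c(0.05, 0.95, 0.95, 0.05) * w,
      y = c(0.02, 0.02, 0.10, 0.10) * w,
      label = "background"
    )
  }
  if (polygons_overlap(lesion_roi, background_roi)) {
    abort("Lesion and background ROIs overlap; choose a clear background region.")
  }
  list(
    map = height_map(z, pixel_spacing = s),
    lesion_roi = lesion_roi,
    background_roi = background_roi,
    truth = shape_truth(shape)
  )
}
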