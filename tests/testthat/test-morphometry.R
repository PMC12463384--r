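# ROI morphometry against closed-form and brute-force oracles.

test_that("plane fit recovers exact and noisy planes", {
  bg <- square_roi(0.2, 0.2, 3.8, 3.8)

  # flat map
  p0 <- fit_reference_plane(flat_map(40, 0.1), bg)
  expect_equal(c(p0$a, p0$b, p0$c, p0$rms_residual), c(0, 0, 0, 0),
               tolerance = 1e-12)

  # exact plane recovered to 1e-9
  p1 <- fit_reference_plane(plane_map(40, 0.1, a = 0.1, b = 0.02, c = 1), bg)
  expect_equal(c(p1$a, p1$b, p1$c), c(0.1, 0.02, 1), tolerance = 1e-9)

  # noisy plane over 10,000 cells: match the normal-equations oracle to 1e-9
  n <- 100L; spacing <- 0.05
  withr::with_seed(42, noise <- matrix(rnorm(n * n, 0, 0.01), n, n))
  xs <- (seq_len(n) - 0.5) * spacing
  z <- outer(xs, xs, function(y, x) 0.3 * x - 0.1 * y + 2) + noise
  map <- height_map(z, spacing)
  roi <- square_roi(0, 0, n * spacing, n * spacing)
  fit <- fit_reference_plane(map, roi)
  X <- cbind(1, rep(xs, each = n), rep(xs, times = n))
  beta <- solve(crossprod(X), crossprod(X, as.vector(z)))
  expect_equal(c(fit$c, fit$a, fit$b), as.vector(beta), tolerance = 1e-9)
  expect_equal(fit$rms_residual, 0.01, tolerance = 0.05)
  expect_equal(fit$n_points_fit, n * n)
})

test_that("degenerate plane fits error out", {
  m <- flat_map(40, 0.1)
  expect_error(fit_reference_plane(m, square_roi(10, 10, 11, 11)),
               "fewer than 3")
  # a sliver one cell wide: all centres collinear
  expect_error(
    fit_reference_plane(m, square_roi(0.21, 0.0, 0.29, 4)),
    "collinear"
  )
})

test_that("volume integration matches analytic caps and brute force", {
  bg <- square_roi(0.2, 0.2, 1.0, 1.0)

  # flat map: all four volumes zero
  plane <- fit_reference_plane(flat_map(60, 0.1), bg)
  v0 <- compute_volumes(flat_map(60, 0.1), square_roi(2, 2, 5, 5, "lesion"),
                        plane)
  expect_equal(unlist(v0[1, 1:4]), setNames(rep(0, 4), names(v0)[1:4]))

  # hemisphere r = 2 at 0.02 mm spacing: within 2% of (2/3) pi 8, negative 0
  sc <- make_lesion_scene(
    lesion_shape("spherical_cap", 2, 2),
    skin_params(grid_size = 300, pixel_spacing = 0.02, noise_sd = 0)
  )
  pl <- fit_reference_plane(sc$map, sc$background_roi)
  v <- compute_volumes(sc$map, sc$lesion_roi, pl)
  expect_equal(v$positive_volume_mm3, 16.7552, tolerance = 0.02)
  expect_equal(v$negative_volume_mm3, 0, tolerance = 1e-9)

  # brute-force per-cell oracle: exact agreement on the same discretisation
  mask <- dermavol:::roi_cell_mask(sc$map, sc$lesion_roi)
  cc <- dermavol:::cell_centers(sc$map)
  res <- as.vector(sc$map$elevations) -
    (pl$a * cc$x + pl$b * cc$y + pl$c)
  brute_pos <- sum(res[as.vector(mask)][res[as.vector(mask)] > 0]) * 0.02^2
  expect_identical(v$positive_volume_mm3, brute_pos)

  # Table 1 printed pair (net 9.11, absolute 9.17) decomposes by the 2x2
  # linear solve into positive 9.14, negative -0.03; check the identities
  pos <- (9.17 + 9.11) / 2; neg <- (9.11 - 9.17) / 2
  expect_equal(pos, 9.14)
  expect_equal(neg, -0.03)
  expect_equal(pos + abs(neg), 9.17)
  expect_equal(pos + neg, 9.11)
})

test_that("empty-interior ROIs error", {
  m <- flat_map(20, 0.1)
  plane <- fit_reference_plane(m, square_roi(0.2, 0.2, 1.8, 1.8))
  expect_error(compute_volumes(m, square_roi(0.101, 0.101, 0.102, 0.102,
                                             "lesion"), plane),
               "no grid-cell centres")
})

test_that("heights follow absolute volume / area and floor at zero", {
  m <- flat_map(30, 0.1)
  plane <- fit_reference_plane(m, square_roi(0.2, 0.2, 2.8, 2.8))
  lesion <- square_roi(1, 1, 2, 2, "lesion")

  h <- compute_heights(m, lesion, plane, absolute_volume_mm3 = 10,
                       surface_area_mm2 = 100)
  expect_equal(h$average_height_mm, 0.1)
  expect_equal(h$max_height_mm, 0)

  expect_error(compute_heights(m, lesion, plane, 10, 0), "> 0")

  # hemisphere: max height r, average height (2/3) r over its disc
  sc <- make_lesion_scene(
    lesion_shape("spherical_cap", 2, 2),
    skin_params(grid_size = 200, pixel_spacing = 0.04, noise_sd = 0)
  )
  pl <- fit_reference_plane(sc$map, sc$background_roi)
  v <- compute_volumes(sc$map, sc$lesion_roi, pl)
  hh <- compute_heights(sc$map, sc$lesion_roi, pl,
                        v$absolute_volume_mm3, pi * 2^2)
  expect_equal(hh$max_height_mm, 2, tolerance = 0.01)
  expect_equal(hh$average_height_mm, 4 / 3, tolerance = 0.02)
})

test_that("Feret diameters match symmetry and the O(n^2) oracle", {
  # regular 360-gon of radius 5: both diameters 10 within 0.01
  circ <- ellipse_roi(c(6, 6), 5, n = 360)
  d <- compute_diameters(circ)
  expect_equal(d$major_diameter_mm, 10, tolerance = 0.001)
  expect_equal(d$perpendicular_diameter_mm, 10, tolerance = 0.001)

  # polygonised ellipse with the worked example's axes 12.9 x 10.1 mm
  ell <- ellipse_roi(c(10, 10), 12.9 / 2, 10.1 / 2, n = 720, angle = 0.4)
  de <- compute_diameters(ell)
  expect_equal(de$major_diameter_mm, 12.9, tolerance = 0.005 * 12.9)
  expect_equal(de$perpendicular_diameter_mm, 10.1, tolerance = 0.005 * 10.1)

  # hull-based major diameter equals brute force over all vertex pairs
  withr::with_seed(7, {
    for (i in 1:200) {
      poly <- random_polygon(sample(5:20, 1))
      major <- compute_diameters(poly)$major_diameter_mm
      d2 <- outer(poly$x_mm, poly$x_mm, `-`)^2 +
        outer(poly$y_mm, poly$y_mm, `-`)^2
      expect_equal(major, sqrt(max(d2)), tolerance = 1e-12)
    }
  })

  # collinear vertices never reach compute_diameters: the constructor rejects
  expect_error(roi_polygon(c(0, 1, 2), c(0, 0, 0), label = "lesion"),
               "zero area")
})

test_that("roughness is the RMS plane residual", {
  bg <- square_roi(0.2, 0.2, 3, 3)
  m <- flat_map(60, 0.1)
  plane <- fit_reference_plane(m, bg)
  lesion <- square_roi(3.5, 3.5, 5.5, 5.5, "lesion")
  expect_equal(compute_roughness(m, lesion, plane), 0)

  # any exact plane, refit on itself: residuals vanish
  pm <- plane_map(60, 0.1, a = 0.2, b = -0.05, c = 3)
  expect_lt(compute_roughness(pm, lesion, fit_reference_plane(pm, bg)), 1e-9)

  # sinusoid of amplitude A over many periods: Rq -> A / sqrt(2) within 1%
  n <- 400L; spacing <- 0.05; A <- 0.3
  xs <- (seq_len(n) - 0.5) * spacing
  zs <- outer(xs, xs, function(y, x) A * sin(2 * pi * x / 1.0))
  sm <- height_map(zs, spacing)
  lesion_big <- square_roi(0, 0, 20, 20, "lesion")
  rq <- compute_roughness(sm, lesion_big, list(a = 0, b = 0, c = 0))
  expect_equal(rq, A / sqrt(2), tolerance = 0.01)
})

test_that("analyze_roi composes the parts and satisfies report invariants", {
  # noise-free tilted skin: |noise| rectification would bias absolute volume
  # upward, so the truth comparison uses the deterministic surface
  sc <- make_lesion_scene(
    lesion_shape("cap_with_ulcer", 1.8, 0.5, ulcer_depth_mm = 0.3),
    skin_params(grid_size = 160, pixel_spacing = 0.05, noise_sd = 0,
                tilt = c(0.05, -0.02), seed = 21)
  )
  rep <- analyze_roi(sc$map, sc$lesion_roi, sc$background_roi)

  expect_equal(rep$absolute_volume_mm3, sc$truth$absolute_volume_mm3,
               tolerance = 0.02)
  expect_lt(rep$negative_volume_mm3, 0)
  expect_gt(rep$absolute_volume_mm3, abs(rep$net_volume_mm3))

  # report identities (machine precision)
  expect_equal(rep$absolute_volume_mm3,
               rep$positive_volume_mm3 + abs(rep$negative_volume_mm3))
  expect_equal(rep$net_volume_mm3,
               rep$positive_volume_mm3 + rep$negative_volume_mm3)
  expect_equal(rep$average_height_mm * rep$surface_area_mm2,
               rep$absolute_volume_mm3)
  expect_lte(rep$perpendicular_diameter_mm, rep$major_diameter_mm)

  # lesion-free scene on a pure plane reports ~0 everywhere
  pm <- plane_map(80, 0.05, a = 0.1, b = 0.02, c = 1)
  rep0 <- analyze_roi(pm, square_roi(1, 1, 3, 3, "lesion"),
                      square_roi(0.2, 3.3, 3.8, 3.9))
  expect_lt(rep0$absolute_volume_mm3, 1e-9)
  expect_lt(rep0$roughness_mm, 1e-9)
})

test_that("reports are invariant to adding a plane to all elevations", {
  sc <- make_lesion_scene(
    lesion_shape("spherical_cap", 1.5, 0.4),
    skin_params(grid_size = 120, pixel_spacing = 0.05, noise_sd = 0.02,
                seed = 4)
  )
  rep1 <- analyze_roi(sc$map, sc$lesion_roi, sc$background_roi)

  cc <- dermavol:::cell_centers(sc$map)
  shifted <- height_map(
    sc$map$elevations + matrix(0.25 * cc$x - 0.4 * cc$y + 3,
                               nrow(sc$map$elevations)),
    sc$map$pixel_spacing
  )
  rep2 <- analyze_roi(shifted, sc$lesion_roi, sc$background_roi)
  for (col in c("surface_area_mm2", "major_diameter_mm",
                "positive_volume_mm3", "negative_volume_mm3",
                "absolute_volume_mm3", "max_height_mm",
                "average_height_mm", "roughness_mm")) {
    expect_equal(rep2[[col]], rep1[[col]], tolerance = 1e-9,
                 label = paste("plane-shifted", col))
  }
})

test_that("hemisphere volume error shrinks monotonically as spacing halves", {
  errs <- vapply(c(0.16, 0.08, 0.04, 0.02), function(sp) {
    sc <- make_lesion_scene(
      lesion_shape("spherical_cap", 2, 2),
      skin_params(grid_size = as.integer(round(6 / sp)), pixel_spacing = sp,
                  noise_sd = 0)
    )
    pl <- fit_reference_plane(sc$map, sc$background_roi)
    v <- compute_volumes(sc$map, sc$lesion_roi, pl)
    abs(v$positive_volume_mm3 - 2 / 3 * pi * 8)
  }, 0)
  expect_true(all(diff(errs) <= 0))
})

test_that("nodata cells are skipped and counted", {
  z <- matrix(1, 40, 40)
  z[15:20, 15:20] <- NA
  m <- height_map(z, 0.1)
  plane <- list(a = 0, b = 0, c = 0)
  v <- compute_volumes(m, square_roi(1, 1, 3, 3, "lesion"), plane)
  expect_equal(v$n_nodata_skipped, 36)
  expect_equal(v$positive_volume_mm3, (v$n_cells) * 0.1^2 * 1)
})
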