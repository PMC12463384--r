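#' Actual phantom volume from mass and density
#'
#' Calibration phantoms are epoxy half-sphere beads weighed on a laboratory
#' balance; their true volume is mass / density, with epoxy density taken as
#' 1.2 mg/mm^3 by default.
#'
#' @param mass_mg Bead mass in mg (> 0); vectorised.
#' @param density_mg_per_mm3 Density in mg/mm^3 (> 0).
#' @returns Volume in mm^3.
#' @examples
#' actual_volume(24)  # 20 mm^3
#' @export
actual_volume <- function(mass_mg, density_mg_per_mm3 = 1.2) {
  if (any(!is.finite(mass_mg)) || any(mass_mg <= 0)) {
    abort("`mass_mg` must be positive.")
  }
  if (any(!is.finite(density_mg_per_mm3)) || any(density_mg_per_mm3 <= 0)) {
    abort("`density_mg_per_mm3` must be positive.")
  }
  mass_mg / density_mg_per_mm3
}

#' Fit the phantom calibration line
#'
#' Ordinary least squares of measured absolute volume on actual (mass
#' derived) volume, the orientation of a measured-vs-actual calibration
#' curve. A slope well below 1 indicates systematic under-estimation by the
#' measurement chain (a vendor stereo reconstruction showed ~0.5); the
#' package's own grid integration should sit very close to 1.
#'
#' @param records Data frame with columns `measured_absvol_mm3` and either
#'   `actual_volume_mm3` or (`mass_mg` + optional `density_mg_per_mm3`).
#' @returns An object of class `calibration_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `n`, and the augmented `records`.
#' @export
fit_calibration <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"measured_absvol_mm3" %in% names(records)) {
    abort("`records` must contain a `measured_absvol_mm3` column.")
  }
  if (!"actual_volume_mm3" %in% names(records)) {
    if (!"mass_mg" %in% names(records)) {
      abort("`records` needs `actual_volume_mm3` or `mass_mg`.")
    }
    density <- records[["density_mg_per_mm3"]] %||% 1.2
    records$actual_volume_mm3 <- actual_volume(records$mass_mg, density)
  }
  if (any(records$measured_absvol_mm3 < 0)) {
    abort("Measured absolute volumes must be >= 0.")
  }
  x <- records$actual_volume_mm3
  y <- records$measured_absvol_mm3
  if (length(unique(x)) < 2L) {
    abort("Need at least 2 distinct actual volumes to fit a calibration line.")
  }
  fit <- lm(y ~ x)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  structure(
    list(
      slope = unname(coef(fit)[["x"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      r_squared = if (sst > 0) 1 - ssr / sst else 1,
      n = length(x),
      records = records
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> measured = %.4g * actual + %.4g  (r^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(.data$actual_volume_mm3,
                               .data$measured_absvol_mm3)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "actual volume (mm³)",
                  y = "measured 3DAbsVol (mm³)",
                  title = sprintf("Calibration: slope %.3f, r² %.3f",
                                  object$slope, object$r_squared))
}

#' Invert the calibration line
#'
#' Maps a measured absolute volume back to the calibrated actual-volume
#' scale: `(measured - intercept) / slope`. Reported for reference but never
#' applied automatically anywhere in the pipeline — clearance and prediction
#' work on relative changes, so the raw measured scale is kept throughout.
#'
#' @param fit A [fit_calibration()] result.
#' @param measured_absvol_mm3 Measured volume(s), mm^3.
#' @returns Corrected volume(s), mm^3.
#' @export
apply_calibration <- function(fit, measured_absvol_mm3) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) abort("Calibration slope is zero; cannot invert.")
  (measured_absvol_mm3 - fit$intercept) / fit$slope
}
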