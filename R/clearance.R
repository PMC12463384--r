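#' Background model and clearance threshold
#'
#' Normal-skin ROIs always report a small nonzero absolute volume (surface
#' micro-texture integrated against the fitted plane). The sample mean and
#' SD of these background readings define the threshold for calling a
#' lesion "disappeared": threshold = mean + k * SD, with k = 1 by default
#' (for the worked clinical example — readings 0.44, 0.59, 0.73 mm^3 — this
#' gives mean 0.59, SD 0.15 and threshold 0.73 mm^3 at full precision).
#'
#' @param readings Numeric vector of background 3DAbsVol readings (mm^3),
#'   at least 2 (the sample SD is undefined otherwise).
#' @param k Multiplier on the SD (>= 0 for a threshold above the mean).
#' @returns A list of class `background_model`: `readings`, `mean`, `sd`
#'   (n-1 denominator), `k`, `threshold`.
#' @examples
#' background_stats(c(0.44, 0.59, 0.73))
#' @export
background_stats <- function(readings, k = 1) {
  readings <- readings[!is.na(readings)]
  if (length(readings) < 2L) {
    abort("Need at least 2 background readings (sample SD undefined).")
  }
  if (any(readings < 0)) abort("Background absolute volumes must be >= 0.")
  m <- mean(readings)
  s <- sd(readings)
  structure(
    list(readings = readings, mean = m, sd = s, k = k,
         threshold = m + k * s),
    class = "background_model"
  )
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "<background_model> mean %.3f +/- %.3f mm^3 (n = %d); threshold mean + %g SD = %.3f mm^3\n",
    x$mean, x$sd, length(x$readings), x$k, x$threshold))
  invisible(x)
}

#' Classify a five-visit lesion trajectory
#'
#' A lesion is *cleared* at the earliest post-treatment visit (V3, V4 or V5)
#' at which its absolute volume is at or below the background threshold and
#' stays at or below it through V5 (sustained clearance: a lesion that dips
#' below threshold and then regrows is a partial responder, not cleared).
#' Sub-threshold values at V1 or V2 — before any treatment could act — never
#' produce a call. Comparison is `<=`, so a value exactly at threshold
#' clears.
#'
#' @param absvol_mm3 Numeric length-5 vector of absolute volumes at visits
#'   V1..V5; no missing values (lesions without all five visits are excluded
#'   upstream).
#' @param background A [background_stats()] model, or a single numeric
#'   threshold in mm^3.
#' @returns One-row tibble (`clearance_call`): `status` ("cleared" /
#'   "not_cleared"), `cleared_visit` (3, 4 or 5; NA when not cleared),
#'   `threshold_mm3`.
#' @examples
#' bg <- background_stats(c(0.44, 0.59, 0.73))
#' classify_clearance(c(9.17, 11.76, 5.73, 0.73, 0.70), bg)
#' @export
classify_clearance <- function(absvol_mm3, background) {
  if (length(absvol_mm3) != 5L || anyNA(absvol_mm3)) {
    abort("`absvol_mm3` must contain exactly 5 non-missing visit values (V1..V5).")
  }
  if (any(absvol_mm3 < 0)) abort("Absolute volumes must be >= 0.")
  thr <- if (inherits(background, "background_model")) {
    background$threshold
  } else if (is.numeric(background) && length(background) == 1L) {
    background
  } else {
    abort("`background` must be a background_model or a single threshold.")
  }
  below <- absvol_mm3 <= thr
  sustained <- rev(cumprod(rev(below))) == 1  # below here and at all later visits
  visit <- which(sustained[3:5])[1L] + 2L
  tibble::tibble(
    status = if (is.na(visit)) "not_cleared" else "cleared",
    cleared_visit = if (is.na(visit)) NA_integer_ else as.integer(visit),
    threshold_mm3 = thr
  )
}

#' Classify every lesion of a long-format cohort table
#'
#' Applies [background_stats()] + [classify_clearance()] per lesion: the
#' lesion's own background readings (column `bkg_reading`, NA where not
#' taken) define its threshold.
#'
#' @param cohort Long-format tibble with columns `patient_id`, `lesion_id`,
#'   `visit` ("V1".."V5"), `absvol_mm3`, `bkg_reading`.
#' @param k SD multiplier passed to [background_stats()].
#' @returns Per-lesion tibble of clearance calls joined to ids (and
#'   `subtype` if present).
#' @export
classify_cohort <- function(cohort, k = 1) {
  cohort <- tibble::as_tibble(cohort)
  need <- c("patient_id", "lesion_id", "visit", "absvol_mm3", "bkg_reading")
  if (!all(need %in% names(cohort))) {
    abort(paste("`cohort` must contain columns:", paste(need, collapse = ", ")))
  }
  cohort |>
    dplyr::group_by(.data$patient_id, .data$lesion_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$visit)
      if (!identical(df$visit, paste0("V", 1:5))) {
        abort(sprintf("Lesion %s/%s does not have exactly visits V1..V5.",
                      key$patient_id, key$lesion_id))
      }
      bg <- background_stats(df$bkg_reading[!is.na(df$bkg_reading)], k = k)
      call <- classify_clearance(df$absvol_mm3, bg)
      if ("subtype" %in% names(df)) call$subtype <- df$subtype[1L]
      call
    }) |>
    dplyr::ungroup()
}

#' Cohort clearance summary
#'
#' Cumulative proportions of lesions cleared by V3, V4 and V5, and the
#' not-cleared (NC) proportion.
#'
#' @param calls Tibble of clearance calls ([classify_clearance()] /
#'   [classify_cohort()] rows).
#' @returns One-row tibble: `n`, `cleared_by_v3`, `cleared_by_v4`,
#'   `cleared_by_v5`, `not_cleared`.
#' @examples
#' calls <- dplyr::bind_rows(
#'   classify_clearance(c(9, 9, 0.5, 0.5, 0.5), 0.74),
#'   classify_clearance(c(9, 9, 9, 9, 9), 0.74)
#' )
#' cohort_clearance_summary(calls)
#' @export
cohort_clearance_summary <- function(calls) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0L) abort("No clearance calls supplied.")
  if (!all(c("status", "cleared_visit") %in% names(calls))) {
    abort("`calls` must contain `status` and `cleared_visit` columns.")
  }
  n <- nrow(calls)
  by <- function(v) sum(!is.na(calls$cleared_visit) & calls$cleared_visit <= v) / n
  tibble::tibble(
    n = n,
    cleared_by_v3 = by(3L),
    cleared_by_v4 = by(4L),
    cleared_by_v5 = by(5L),
    not_cleared = 1 - by(5L)
  )
}
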