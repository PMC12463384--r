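#' Confusion counts at a size threshold
#'
#' A lesion is *predicted* to respond to PDT when its baseline size
#' predictor (3DAbsVol or 3DAvHt at V1) is at or below the threshold —
#' small, thin lesions respond; ties at the threshold count as predicted
#' responders. Actual response is complete clearance by V5.
#'
#' @param records Tibble with a logical `actual_responder` column and the
#'   predictor column.
#' @param predictor Name of the predictor column (e.g. `"avht_v1_mm"` or
#'   `"absvol_v1_mm3"`).
#' @param threshold Numeric cutoff in the predictor's units.
#' @returns One-row tibble: `tp`, `fn`, `tn`, `fp`, `threshold`,
#'   `predictor`.
#' @export
confusion_at_threshold <- function(records, predictor, threshold) {
  records <- tibble::as_tibble(records)
  if (!predictor %in% names(records)) {
    abort(paste0("Predictor column '", predictor, "' not found."))
  }
  if (!"actual_responder" %in% names(records)) {
    abort("`records` must contain a logical `actual_responder` column.")
  }
  x <- records[[predictor]]
  if (anyNA(x)) {
    bad <- records$lesion_id[is.na(x)] %||% which(is.na(x))
    abort(paste0("Missing '", predictor, "' for lesion(s): ",
                 paste(bad, collapse = ", ")))
  }
  predicted <- x <= threshold
  actual <- records$actual_responder
  tibble::tibble(
    tp = sum(predicted & actual),
    fn = sum(!predicted & actual),
    tn = sum(!predicted & !actual),
    fp = sum(predicted & !actual),
    threshold = threshold,
    predictor = predictor
  )
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity = tp / (tp + fn), over actual responders; specificity =
#' tn / (tn + fp), over actual nonresponders. Errors when either class is
#' empty (the rate is undefined).
#'
#' @param counts One-row tibble or list with `tp`, `fn`, `tn`, `fp`.
#' @returns One-row tibble: `sensitivity`, `specificity`.
#' @examples
#' sens_spec(list(tp = 9, fn = 1, tn = 5, fp = 5))
#' @export
sens_spec <- function(counts) {
  if (counts$tp + counts$fn == 0) abort("No actual responders; sensitivity undefined.")
  if (counts$tn + counts$fp == 0) abort("No actual nonresponders; specificity undefined.")
  tibble::tibble(
    sensitivity = counts$tp / (counts$tp + counts$fn),
    specificity = counts$tn / (counts$tn + counts$fp)
  )
}

#' Operational threshold: where sensitivity and specificity meet
#'
#' Sweeps every distinct predictor value plus the midpoints between
#' consecutive values, computing sensitivity and specificity at each, and
#' picks the candidate minimising |sensitivity - specificity| (ties broken
#' toward the smaller threshold). With the <= orientation, sensitivity is
#' non-decreasing and specificity non-increasing in the threshold, so the
#' minimiser is the operating point where the two curves cross.
#'
#' @inheritParams confusion_at_threshold
#' @returns An object of class `threshold_analysis`: `sweep` (tibble of
#'   threshold / sensitivity / specificity), `operational_threshold`,
#'   `sens_at_operational`, `spec_at_operational`, `predictor`, `n`.
#' @export
operational_threshold <- function(records, predictor) {
  records <- tibble::as_tibble(records)
  if (!predictor %in% names(records)) {
    abort(paste0("Predictor column '", predictor, "' not found."))
  }
  x <- records[[predictor]]
  actual <- records$actual_responder
  n_resp <- sum(actual); n_non <- sum(!actual)
  if (n_resp == 0 || n_non == 0) {
    abort("Both responders and nonresponders are required for a threshold sweep.")
  }
  v <- sort(unique(x))
  cand <- sort(unique(c(v, head(v, -1L) + diff(v) / 2)))
  # counts below each candidate via cumulative counts of sorted class values
  sens <- vapply(cand, function(t) sum(x[actual] <= t), 0) / n_resp
  spec <- vapply(cand, function(t) sum(x[!actual] > t), 0) / n_non
  sweep <- tibble::tibble(threshold = cand, sensitivity = sens,
                          specificity = spec)
  best <- which.min(abs(sens - spec))  # which.min takes the first = smallest t
  structure(
    list(sweep = sweep,
         operational_threshold = cand[best],
         sens_at_operational = sens[best],
         spec_at_operational = spec[best],
         predictor = predictor, n = length(x)),
    class = "threshold_analysis"
  )
}

#' @export
print.threshold_analysis <- function(x, ...) {
  cat(sprintf(
    "<threshold_analysis> %s: operational threshold %.4g (sens %.1f%%, spec %.1f%%, n = %d)\n",
    x$predictor, x$operational_threshold, 100 * x$sens_at_operational,
    100 * x$spec_at_operational, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.threshold_analysis <- function(x, ...) x$sweep

#' @exportS3Method generics::glance
glance.threshold_analysis <- function(x, ...) {
  tibble::tibble(
    predictor = x$predictor,
    operational_threshold = x$operational_threshold,
    sensitivity = x$sens_at_operational,
    specificity = x$spec_at_operational,
    n = x$n
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.threshold_analysis <- function(object, ...) {
  df <- tidyr::pivot_longer(object$sweep, c("sensitivity", "specificity"),
                            names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$operational_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = object$predictor, y = NULL,
                  title = sprintf("Operational threshold %.3g",
                                  object$operational_threshold))
}

#' Drop aggressive BCC subtypes
#'
#' Micronodular and infiltrative BCC — the aggressive growth patterns — are
#' assumed pre-identified by biopsy in clinical practice and excluded from
#' PDT; removing them from the analysis raises specificity because most
#' nonresponders misclassified as "thin, should respond" are aggressive.
#'
#' @param records Tibble with a `subtype` column among superficial, nodular,
#'   micronodular, infiltrative, other.
#' @returns Filtered copy of `records`; the number removed is reported as a
#'   message and attached as attribute `"n_removed"`.
#' @export
exclude_aggressive <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"subtype" %in% names(records)) abort("`records` must have a `subtype` column.")
  known <- c("superficial", "nodular", "micronodular", "infiltrative", "other")
  bad <- setdiff(unique(records$subtype), known)
  if (length(bad)) {
    abort(paste0("Unknown subtype label(s): ", paste(bad, collapse = ", ")))
  }
  keep <- !records$subtype %in% c("micronodular", "infiltrative")
  out <- records[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (nrow(out) == 0L) warn("All lesions were aggressive; returning an empty cohort.")
  message(sprintf("Excluded %d aggressive (micronodular/infiltrative) lesion(s).",
                  n_removed))
  attr(out, "n_removed") <- n_removed
  out
}

#' Average height versus histological depth
#'
#' OLS regression of baseline 3DAvHt on histological tumor depth, the
#' Pearson correlation, and the mean avht/depth ratio. Average heights run
#' roughly 10–20% of the true depth: the surface relief is a scaled-down
#' but linearly related surrogate of how deep the tumor grows.
#'
#' @param pairs Tibble with columns `avht_mm` and `depth_mm` (n >= 3,
#'   depths > 0).
#' @returns An object of class `depth_correlation`: `slope`, `intercept`,
#'   `pearson_r`, `ratio_summary` (mean avht/depth), `n`, `pairs`.
#' @export
depth_correlation <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("avht_mm", "depth_mm") %in% names(pairs))) {
    abort("`pairs` must have columns `avht_mm` and `depth_mm`.")
  }
  pairs <- pairs[!is.na(pairs$avht_mm) & !is.na(pairs$depth_mm), ]
  if (nrow(pairs) < 3L) abort("Need at least 3 (avht, depth) pairs.")
  if (any(pairs$depth_mm <= 0)) abort("Depths must be > 0.")
  if (sd(pairs$depth_mm) == 0) abort("Zero-variance depth; correlation undefined.")
  fit <- lm(avht_mm ~ depth_mm, data = pairs)
  structure(
    list(slope = unname(coef(fit)[["depth_mm"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         pearson_r = stats::cor(pairs$avht_mm, pairs$depth_mm),
         ratio_summary = mean(pairs$avht_mm / pairs$depth_mm),
         n = nrow(pairs), pairs = pairs),
    class = "depth_correlation"
  )
}

#' @export
print.depth_correlation <- function(x, ...) {
  cat(sprintf(
    "<depth_correlation> avht = %.4g * depth + %.4g  (r = %.3f, mean ratio %.3f, n = %d)\n",
    x$slope, x$intercept, x$pearson_r, x$ratio_summary, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.depth_correlation <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.depth_correlation <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 pearson_r = x$pearson_r, ratio_summary = x$ratio_summary,
                 n = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.depth_correlation <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$depth_mm, .data$avht_mm)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "histological depth (mm)", y = "3DAvHt (mm)",
                  title = sprintf("slope %.3f, r = %.3f",
                                  object$slope, object$pearson_r))
}
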