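#' Pipeline configuration
#'
#' Collects everything the end-to-end run needs: the synthetic cohort's
#' stated world (or a path to a real cohort CSV), the clearance rule's SD
#' multiplier, the predictors to sweep, and the master seed every stage's
#' randomness derives from.
#'
#' @param cohort Either `NULL` (simulate with `params`), a path to a cohort
#'   CSV, or a long-format data frame.
#' @param params A [cohort_params()] used when simulating.
#' @param k_sd SD multiplier for the background threshold.
#' @param predictors Predictor columns to sweep at baseline.
#' @param exclude_aggressive Also compute operating points after dropping
#'   micronodular/infiltrative lesions.
#' @param background_sd_mm3 Background noise for the simulated series.
#' @param seed Master integer seed.
#' @returns A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, params = cohort_params(),
                            k_sd = 1, predictors = c("absvol_v1_mm3",
                                                     "avht_v1_mm"),
                            exclude_aggressive = TRUE,
                            background_sd_mm3 = 0.15, seed = 1L) {
  if (!is.null(params) && !inherits(params, "cohort_params")) {
    abort("`params` must be a cohort_params() object.")
  }
  if (is.null(cohort) && params$n_lesions < 1L) {
    abort("Simulated cohorts need `params$n_lesions` >= 1.")
  }
  structure(
    list(cohort = cohort, params = params, k_sd = k_sd,
         predictors = predictors, exclude_aggressive = exclude_aggressive,
         background_sd_mm3 = background_sd_mm3, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' simulation (or ingest) -> exclusion accounting -> per-lesion clearance
#' classification -> cohort clearance summary -> baseline size-threshold
#' sweeps (with and without aggressive subtypes) -> height-vs-depth
#' correlation. Deterministic under a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage's table is
#'   written there as CSV plus a `summary.json` with provenance (seed,
#'   config hash).
#' @returns A list of class `pipeline_result`: `cohort_table`, `baseline`,
#'   `calls`, `clearance_summary`, `thresholds` (glance rows per predictor
#'   and cohort subset), `sweeps`, `depth`, `truth` (when simulated),
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (is.null(config$cohort)) {
    params <- config$params
    params$seed <- config$seed
    cohort <- make_cohort(params)
    truth <- cohort
    long <- make_cohort_series(cohort,
                               background_sd_mm3 = config$background_sd_mm3,
                               seed = config$seed + 1L)
  } else {
    long <- config$cohort
  }
  ct <- read_cohort(long)

  calls <- classify_cohort(ct$cohort, k = config$k_sd)
  summary_tbl <- cohort_clearance_summary(calls)

  # baseline (V1) record per lesion, joined to the clearance outcome
  baseline <- ct$cohort |>
    dplyr::filter(.data$visit == "V1") |>
    dplyr::select(dplyr::any_of(c("patient_id", "lesion_id", "subtype",
                                  "depth_mm", "absvol_mm3", "avht_mm"))) |>
    dplyr::rename(absvol_v1_mm3 = "absvol_mm3") |>
    dplyr::left_join(calls[, c("patient_id", "lesion_id", "status",
                               "cleared_visit")],
                     by = c("patient_id", "lesion_id")) |>
    dplyr::mutate(actual_responder = .data$status == "cleared")
  if ("avht_mm" %in% names(baseline)) {
    baseline <- dplyr::rename(baseline, avht_v1_mm = "avht_mm")
  }

  predictors <- intersect(config$predictors, names(baseline))
  sweeps <- list()
  thresholds <- purrr::map_dfr(predictors, function(p) {
    ta <- operational_threshold(baseline, p)
    sweeps[[paste0(p, "_all")]] <<- ta$sweep
    dplyr::mutate(glance(ta), cohort = "all")
  })
  if (isTRUE(config$exclude_aggressive) && "subtype" %in% names(baseline)) {
    kept <- suppressMessages(exclude_aggressive(baseline))
    if (nrow(kept) > 0L &&
        length(unique(kept$actual_responder)) == 2L) {
      thresholds <- dplyr::bind_rows(
        thresholds,
        purrr::map_dfr(predictors, function(p) {
          ta <- operational_threshold(kept, p)
          sweeps[[paste0(p, "_no_aggressive")]] <<- ta$sweep
          dplyr::mutate(glance(ta), cohort = "no_aggressive")
        })
      )
    }
  }

  depth <- NULL
  if (all(c("depth_mm", "avht_v1_mm") %in% names(baseline)) &&
      sum(!is.na(baseline$depth_mm)) >= 3L) {
    depth <- depth_correlation(
      tibble::tibble(avht_mm = baseline$avht_v1_mm,
                     depth_mm = baseline$depth_mm)
    )
  }

  provenance <- list(
    seed = config$seed,
    k_sd = config$k_sd,
    config_hash = rlang::hash(config[setdiff(names(config), "cohort")]),
    n_input_lesions = ct$n_input_lesions,
    n_analyzable = ct$n_input_lesions - nrow(ct$exclusions),
    package_version = as.character(utils::packageVersion("dermavol"))
  )
  result <- structure(
    list(cohort_table = ct, baseline = baseline, calls = calls,
         clearance_summary = summary_tbl, thresholds = thresholds,
         sweeps = sweeps, depth = depth, truth = truth,
         provenance = provenance),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_result_bundle(result, out_dir)
  result
}

write_result_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(as.data.frame(df), file.path(out_dir, name),
                     row.names = FALSE)
  }
  w(result$cohort_table$cohort, "cohort.csv")
  w(result$cohort_table$exclusions, "exclusions.csv")
  w(result$calls, "clearance_calls.csv")
  w(result$thresholds, "thresholds.csv")
  for (nm in names(result$sweeps)) w(result$sweeps[[nm]],
                                     paste0("sweep_", nm, ".csv"))
  summary <- c(
    result$provenance,
    as.list(result$clearance_summary),
    if (!is.null(result$depth)) list(depth = as.list(glance(result$depth)))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_report(result, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$clearance_summary
  cat(sprintf(
    "<pipeline_result> %d analyzable lesions; cleared by V3/V4/V5: %.0f%% / %.0f%% / %.0f%% (NC %.0f%%)\n",
    s$n, 100 * s$cleared_by_v3, 100 * s$cleared_by_v4,
    100 * s$cleared_by_v5, 100 * s$not_cleared))
  if (nrow(x$thresholds)) {
    print(x$thresholds)
  }
  invisible(x)
}

#' Plain-text report of a pipeline run
#'
#' A human-readable summary: exclusion accounting, cumulative clearance,
#' operating points per predictor, depth correlation, and one worked
#' per-lesion example in the wide visit layout with its clearance call.
#'
#' @param result A [run_pipeline()] result.
#' @param path Output file path.
#' @returns `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  s <- result$clearance_summary
  ct <- result$cohort_table
  lines <- c(
    "dermavol pipeline report",
    sprintf("seed %d | config %s | package %s",
            result$provenance$seed, result$provenance$config_hash,
            result$provenance$package_version),
    "",
    sprintf("Lesions: %d input, %d excluded, %d analyzable",
            ct$n_input_lesions, nrow(ct$exclusions), s$n),
    if (nrow(ct$exclusions)) {
      paste0("  excluded - ",
             paste(names(table(ct$exclusions$reason)),
                   table(ct$exclusions$reason), sep = ": ", collapse = ", "))
    },
    "",
    sprintf("Cumulative clearance: V3 %.0f%%, V4 %.0f%%, V5 %.0f%%; not cleared %.0f%%",
            100 * s$cleared_by_v3, 100 * s$cleared_by_v4,
            100 * s$cleared_by_v5, 100 * s$not_cleared),
    ""
  )
  if (nrow(result$thresholds)) {
    lines <- c(lines, "Operating points (sensitivity ~ specificity):",
               vapply(seq_len(nrow(result$thresholds)), function(i) {
                 r <- result$thresholds[i, ]
                 sprintf("  %-16s [%s] threshold %.4g -> sens %.0f%%, spec %.0f%%",
                         r$predictor, r$cohort, r$operational_threshold,
                         100 * r$sensitivity, 100 * r$specificity)
               }, ""), "")
  }
  if (!is.null(result$depth)) {
    d <- result$depth
    lines <- c(lines, sprintf(
      "Height vs depth: slope %.3f, r = %.3f, mean avht/depth = %.3f (n = %d)",
      d$slope, d$pearson_r, d$ratio_summary, d$n), "")
  }
  ex <- result$calls[1L, ]
  wide <- lesion_wide_view(ct$cohort, ex$patient_id, ex$lesion_id)
  lines <- c(
    lines,
    sprintf("Worked example: patient %s, lesion %s", ex$patient_id,
            ex$lesion_id),
    utils::capture.output(print(as.data.frame(wide), row.names = FALSE)),
    if (ex$status == "cleared") {
      sprintf("  ----- Lesion cleared at V%d (threshold %.3f mm^3) -----",
              ex$cleared_visit, ex$threshold_mm3)
    } else {
      sprintf("  ----- Lesion not cleared (threshold %.3f mm^3) -----",
              ex$threshold_mm3)
    }
  )
  writeLines(lines[!vapply(lines, is.null, TRUE)], path)
  invisible(path)
}
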