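#' Read and validate a long-format cohort table
#'
#' One row per lesion-visit. Required columns (case-insensitive):
#' `patient_id`, `lesion_id`, `visit` (V1..V5), `absvol_mm3`,
#' `bkg_reading`, `subtype`; extra columns are kept. Rows failing the
#' study's eligibility rules are routed to an exclusion report rather than
#' silently dropped, mirroring the raw-to-analyzable accounting of a
#' clinical trial (non-BCC diagnosis; incomplete visit coverage).
#'
#' @param x Path to a CSV file, or a data frame.
#' @returns A list of class `cohort_table`: `cohort` (validated analyzable
#'   long tibble), `exclusions` (tibble: `patient_id`, `lesion_id`,
#'   `reason`), `n_input_lesions`.
#' @export
read_cohort <- function(x) {
  df <- if (is.character(x)) {
    tibble::as_tibble(utils::read.csv(x, stringsAsFactors = FALSE))
  } else {
    tibble::as_tibble(x)
  }
  names(df) <- tolower(names(df))
  need <- c("patient_id", "lesion_id", "visit", "absvol_mm3", "bkg_reading",
            "subtype")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste("Cohort table is missing column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  if (!all(df$visit %in% paste0("V", 1:5))) {
    bad <- setdiff(unique(df$visit), paste0("V", 1:5))
    abort(paste("Unknown visit label(s):", paste(bad, collapse = ", ")))
  }
  key <- paste(df$patient_id, df$lesion_id, df$visit)
  if (anyDuplicated(key)) {
    abort(paste("Duplicate (patient, lesion, visit) rows:",
                paste(unique(key[duplicated(key)]), collapse = "; ")))
  }

  bcc_subtypes <- c("superficial", "nodular", "micronodular", "infiltrative",
                    "other")
  per_lesion <- df |>
    dplyr::group_by(.data$patient_id, .data$lesion_id) |>
    dplyr::summarise(
      n_visits = dplyr::n_distinct(.data$visit),
      non_bcc = !all(.data$subtype %in% bcc_subtypes),
      .groups = "drop"
    )
  per_lesion$reason <- dplyr::case_when(
    per_lesion$non_bcc ~ "non-BCC diagnosis",
    per_lesion$n_visits < 5L ~ "incomplete visits",
    TRUE ~ NA_character_
  )
  exclusions <- per_lesion |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("patient_id", "lesion_id", "reason")
  cohort <- df |>
    dplyr::anti_join(exclusions, by = c("patient_id", "lesion_id")) |>
    dplyr::arrange(.data$patient_id, .data$lesion_id, .data$visit)
  structure(
    list(cohort = cohort, exclusions = exclusions,
         n_input_lesions = nrow(per_lesion)),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "<cohort_table> %d input lesions: %d analyzable, %d excluded (%s)\n",
    x$n_input_lesions,
    x$n_input_lesions - nrow(x$exclusions),
    nrow(x$exclusions),
    if (nrow(x$exclusions)) {
      paste(names(table(x$exclusions$reason)), table(x$exclusions$reason),
            sep = ": ", collapse = ", ")
    } else "none"
  ))
  invisible(x)
}

#' @rdname read_cohort
#' @param cohort Long-format cohort tibble.
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Widen a lesion's visit series into the worked-example row layout
#'
#' Converts the long per-visit rows of a single lesion into one wide row per
#' measured quantity (absolute volume, average height, background readings),
#' the layout clinical worked examples are printed in.
#'
#' @param cohort Long cohort tibble.
#' @param patient_id,lesion_id Which lesion.
#' @returns A wide tibble with a `parameter` column and V1..V5 columns.
#' @export
lesion_wide_view <- function(cohort, patient_id, lesion_id) {
  df <- cohort[cohort$patient_id == patient_id &
                 cohort$lesion_id == lesion_id, , drop = FALSE]
  if (nrow(df) == 0L) abort("No rows for that (patient_id, lesion_id).")
  keep <- intersect(c("absvol_mm3", "avht_mm", "bkg_reading"), names(df))
  df |>
    dplyr::select("visit", dplyr::all_of(keep)) |>
    tidyr::pivot_longer(-"visit", names_to = "parameter") |>
    tidyr::pivot_wider(names_from = "visit", values_from = "value")
}
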