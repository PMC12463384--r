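#' Visit-kinetics profile for one synthetic lesion
#'
#' Five-visit absolute-volume trajectories follow one of four response
#' archetypes seen clinically: complete responders that shrink to the
#' normal-skin background level and stay there; partial regrowers that dip
#' after one or more treatments but grow back; nonresponders that keep
#' growing; and thin aggressive nonresponders — small, flat lesions of
#' aggressive histology that grow steadily despite treatment.
#'
#' Default multipliers for the complete responder mirror the worked clinical
#' example (rise before the first treatment, then fall to background).
#'
#' @param archetype One of `"complete_responder"`, `"partial_regrower"`,
#'   `"nonresponder"`, `"thin_aggressive_nonresponder"`.
#' @param baseline_absvol_mm3 V1 absolute volume (mm^3, >= 0).
#' @param multipliers Length-5 non-negative per-visit multipliers on the
#'   baseline; defaults depend on the archetype.
#' @param background_level_mm3,background_sd_mm3 Mean and SD of normal-skin
#'   background readings (mm^3); defaults 0.59 and 0.15.
#' @param measurement_sd_mm3 SD of additive measurement noise on each visit
#'   volume; defaults to `background_sd_mm3`.
#' @returns A list of class `kinetics_profile`.
#' @export
kinetics_profile <- function(archetype = c("complete_responder",
                                           "partial_regrower",
                                           "nonresponder",
                                           "thin_aggressive_nonresponder"),
                             baseline_absvol_mm3 = NULL,
                             multipliers = NULL,
                             background_level_mm3 = 0.59,
                             background_sd_mm3 = 0.15,
                             measurement_sd_mm3 = background_sd_mm3) {
  archetype <- match.arg(archetype)
  defaults <- list(
    complete_responder = list(baseline = 9.17,
                              mult = c(1, 1.28, 0.62, 0.08, 0.08)),
    partial_regrower = list(baseline = 8,
                            mult = c(1, 1.10, 0.45, 0.35, 0.95)),
    nonresponder = list(baseline = 15,
                        mult = c(1, 1.05, 1.15, 1.25, 1.30)),
    thin_aggressive_nonresponder = list(baseline = 1.8,
                                        mult = c(1, 1.3, 1.7, 2.2, 2.8))
  )[[archetype]]
  baseline_absvol_mm3 <- baseline_absvol_mm3 %||% defaults$baseline
  multipliers <- multipliers %||% defaults$mult
  if (baseline_absvol_mm3 < 0) abort("`baseline_absvol_mm3` must be >= 0.")
  if (length(multipliers) != 5L || any(multipliers < 0)) {
    abort("`multipliers` must be 5 non-negative values.")
  }
  if (background_sd_mm3 < 0 || measurement_sd_mm3 < 0) {
    abort("Noise SDs must be >= 0.")
  }
  structure(
    list(archetype = archetype,
         baseline_absvol_mm3 = baseline_absvol_mm3,
         multipliers = multipliers,
         background_level_mm3 = background_level_mm3,
         background_sd_mm3 = background_sd_mm3,
         measurement_sd_mm3 = measurement_sd_mm3),
    class = "kinetics_profile"
  )
}

#' Simulate one lesion's five-visit series
#'
#' Per-visit absolute volume = baseline x multiplier + Gaussian measurement
#' noise, floored at the background level (an absolute volume can never read
#' below the skin's own texture). Background readings are drawn
#' `|N(mean, sd)|` at visits 1, 2 and 5, mimicking when they are taken in
#' clinic.
#'
#' @param profile A [kinetics_profile()].
#' @param seed Integer seed; identical seeds give identical series.
#' @returns Tibble with columns `visit` ("V1".."V5"), `absvol_mm3`,
#'   `bkg_reading` (NA at V3/V4); the profile is attached as attribute
#'   `"profile"`.
#' @export
make_visit_series <- function(profile, seed = 1L) {
  stopifnot(inherits(profile, "kinetics_profile"))
  withr::with_seed(seed, {
    vol <- profile$baseline_absvol_mm3 * profile$multipliers +
      rnorm(5L, 0, profile$measurement_sd_mm3)
    vol <- pmax(vol, profile$background_level_mm3)
    bkg <- abs(rnorm(3L, profile$background_level_mm3,
                     profile$background_sd_mm3))
  })
  out <- tibble::tibble(
    visit = paste0("V", 1:5),
    absvol_mm3 = vol,
    bkg_reading = c(bkg[1L], bkg[2L], NA, NA, bkg[3L])
  )
  attr(out, "profile") <- profile
  out
}

#' Cohort generator parameters
#'
#' The stated world of the synthetic cohort: histological subtype mixture as
#' observed clinically (superficial 31%, nodular 44%, micronodular 15%,
#' infiltrative 5%, other 7% — printed percentages that sum to 102%, so the
#' default mix is normalised to sum to 1); baseline average height drawn
#' `N(0.15, 0.06)` mm truncated at 0.01 (symmetric about the responder
#' midpoint, which pins the sensitivity = specificity crossing at the
#' midpoint); histological depth = avht / depth_ratio + noise, with heights
#' 10–20% of true depth; responder probability a decreasing logistic in
#' baseline average height with midpoint 0.15 mm.
#'
#' @param n_lesions Number of lesions (>= 1); the study scale is 122.
#' @param subtype_mix Named proportions for superficial, nodular,
#'   micronodular, infiltrative, other; must sum to 1 (tolerance 1e-9).
#' @param depth_ratio True avht/depth proportionality, in (0, 1).
#' @param depth_noise_sd SD of additive depth noise (mm).
#' @param responder_midpoint,responder_scale Logistic midpoint and scale
#'   (mm) of the responder-probability curve
#'   `p = plogis((midpoint - avht) / scale)`.
#' @param avht_mean,avht_sd Baseline average-height distribution (mm).
#' @param aggressive_thin If `TRUE`, micronodular/infiltrative lesions are
#'   planted as thin nonresponders (small avht, responder = FALSE),
#'   mimicking the clinical mechanism that degrades specificity until they
#'   are excluded.
#' @param seed Integer seed.
#' @returns A list of class `cohort_params`.
#' @export
cohort_params <- function(n_lesions = 122L,
                          subtype_mix = c(superficial = 0.31, nodular = 0.44,
                                          micronodular = 0.15,
                                          infiltrative = 0.05,
                                          other = 0.07) / 1.02,
                          depth_ratio = 0.15, depth_noise_sd = 0.15,
                          responder_midpoint = 0.15, responder_scale = 0.05,
                          avht_mean = 0.15, avht_sd = 0.06,
                          aggressive_thin = FALSE, seed = 1L) {
  if (n_lesions < 1L) abort("`n_lesions` must be >= 1.")
  if (abs(sum(subtype_mix) - 1) > 1e-9) {
    abort("`subtype_mix` proportions must sum to 1 (tolerance 1e-9).")
  }
  if (depth_ratio <= 0 || depth_ratio >= 1) {
    abort("`depth_ratio` must lie in (0, 1).")
  }
  structure(
    list(n_lesions = as.integer(n_lesions), subtype_mix = subtype_mix,
         depth_ratio = depth_ratio, depth_noise_sd = depth_noise_sd,
         responder_midpoint = responder_midpoint,
         responder_scale = responder_scale,
         avht_mean = avht_mean, avht_sd = avht_sd,
         aggressive_thin = aggressive_thin, seed = as.integer(seed)),
    class = "cohort_params"
  )
}

#' Simulate a per-lesion cohort with ground truth
#'
#' One row per lesion: subtype (multinomial at the requested mix), baseline
#' average height and absolute volume, histological depth, the latent
#' responder probability and the planted true responder status. Baseline
#' absolute volume is avht times a lognormal lesion ROI area (clinical ROIs
#' run tens to a couple of hundred mm^2).
#'
#' @param params A [cohort_params()].
#' @returns Tibble with columns `lesion_id`, `patient_id`, `subtype`,
#'   `avht_v1_mm`, `area_mm2`, `absvol_v1_mm3`, `depth_mm`,
#'   `p_responder`, `actual_responder`.
#' @export
make_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_lesions
  withr::with_seed(params$seed, {
    subtype <- sample(names(params$subtype_mix), n, replace = TRUE,
                      prob = params$subtype_mix)
    avht <- pmax(rnorm(n, params$avht_mean, params$avht_sd), 0.01)
    aggressive <- subtype %in% c("micronodular", "infiltrative")
    if (params$aggressive_thin) {
      # thin aggressive lesions: low surface height despite deep growth
      avht[aggressive] <- pmax(rnorm(sum(aggressive), 0.06, 0.02), 0.01)
    }
    p <- plogis((params$responder_midpoint - avht) / params$responder_scale)
    responder <- runif(n) < p
    if (params$aggressive_thin) responder[aggressive] <- FALSE
    area <- exp(rnorm(n, log(80), 0.5))
    depth <- pmax(avht / params$depth_ratio +
                    rnorm(n, 0, params$depth_noise_sd), 0.05)
  })
  tibble::tibble(
    lesion_id = sprintf("L%03d", seq_len(n)),
    patient_id = sprintf("P%03d", (seq_len(n) - 1L) %/% 4L + 1L),
    subtype = subtype,
    avht_v1_mm = avht,
    area_mm2 = area,
    absvol_v1_mm3 = avht * area,
    depth_mm = depth,
    p_responder = p,
    actual_responder = responder
  )
}

# Trajectory multipliers for a planted clearance visit / nonresponse.
planted_multipliers <- function(cleared_visit) {
  switch(as.character(cleared_visit),
    "3" = c(1, 1.10, 0.05, 0.04, 0.04),
    "4" = c(1, 1.20, 0.60, 0.06, 0.05),
    "5" = c(1, 1.10, 0.70, 0.40, 0.05),
    abort("`cleared_visit` must be 3, 4 or 5.")
  )
}

#' Expand a cohort into a long lesion-visit table
#'
#' Gives every lesion of [make_cohort()] a five-visit trajectory consistent
#' with its planted responder status: responders clear at V3/V4/V5 (59/24/17
#' split among responders, matching the clinical pattern of most clearances
#' being noticed early) with post-clearance volumes parked below the
#' background mean; nonresponders follow the nonresponder or
#' partial-regrower archetype and stay above threshold at V5. Background
#' readings are drawn per lesion.
#'
#' @param cohort A [make_cohort()] tibble.
#' @param background_level_mm3,background_sd_mm3 Background reading model
#'   (mm^3); `background_sd_mm3 = 0` gives noise-free trajectories that the
#'   clearance classifier recovers essentially perfectly.
#' @param seed Integer seed.
#' @returns Long tibble: one row per lesion-visit with `patient_id`,
#'   `lesion_id`, `visit`, `absvol_mm3`, `avht_mm`, `bkg_reading`,
#'   `subtype`, `depth_mm`, plus the planted `true_cleared_visit` (NA for
#'   nonresponders).
#' @export
make_cohort_series <- function(cohort, background_level_mm3 = 0.59,
                               background_sd_mm3 = 0.15, seed = 1L) {
  cohort <- tibble::as_tibble(cohort)
  n <- nrow(cohort)
  withr::with_seed(seed, {
    cleared_visit <- ifelse(
      cohort$actual_responder,
      sample(c(3L, 4L, 5L), n, replace = TRUE, prob = c(0.59, 0.24, 0.17)),
      NA_integer_
    )
    regrower <- !cohort$actual_responder & runif(n) < 0.5
    lesion_seeds <- sample.int(2^31 - 1L, n)
  })
  rows <- purrr::pmap(
    list(seq_len(n), cleared_visit, regrower, lesion_seeds),
    function(i, cv, rg, ls) {
      base <- max(cohort$absvol_v1_mm3[i], 3 * background_level_mm3)
      withr::with_seed(ls, {
        if (!is.na(cv)) {
          mult <- planted_multipliers(cv)
          vol <- base * mult
          pre <- seq_len(cv - 1L)
          vol[pre] <- pmax(vol[pre] + rnorm(cv - 1L, 0, background_sd_mm3),
                           1.5 * background_level_mm3)
          # post-clearance: sub-background-mean readings, sustained
          post <- cv:5L
          vol[post] <- background_level_mm3 * runif(length(post), 0.5, 0.95)
        } else {
          mult <- if (rg) c(1, 1.10, 0.45, 0.70, 1.05)
                  else c(1, 1.05, 1.15, 1.25, 1.30)
          vol <- pmax(base * mult + rnorm(5L, 0, background_sd_mm3),
                      1.5 * background_level_mm3)
        }
        bkg3 <- abs(rnorm(3L, background_level_mm3, background_sd_mm3))
      })
      tibble::tibble(
        patient_id = cohort$patient_id[i],
        lesion_id = cohort$lesion_id[i],
        visit = paste0("V", 1:5),
        absvol_mm3 = vol,
        avht_mm = vol / cohort$area_mm2[i],
        bkg_reading = c(bkg3[1L], bkg3[2L], NA, NA, bkg3[3L]),
        subtype = cohort$subtype[i],
        depth_mm = cohort$depth_mm[i],
        true_cleared_visit = cv
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Simulate a raw (pre-exclusion) cohort table
#'
#' Emulates the raw accounting of a clinical study: on top of
#' `n_analyzable` complete BCC lesions, adds lesions later excluded for a
#' non-BCC diagnosis (SCC, fibrosis/scar) and lesions with incomplete visit
#' coverage, so that [read_cohort()]'s exclusion report can be exercised
#' (the study went 211 -> 122).
#'
#' @param n_analyzable Complete, analyzable BCC lesions.
#' @param n_non_bcc Lesions with a non-BCC diagnosis.
#' @param n_incomplete Lesions missing at least one visit.
#' @param params Optional [cohort_params()] (its `n_lesions` is overridden
#'   by `n_analyzable`).
#' @param background_sd_mm3 Background noise for the visit series.
#' @param seed Integer seed.
#' @returns A list: `table` (long tibble, shuffled), `truth` (the analyzable
#'   cohort with planted ground truth).
#' @export
simulate_raw_cohort <- function(n_analyzable = 122L, n_non_bcc = 40L,
                                n_incomplete = 49L, params = NULL,
                                background_sd_mm3 = 0.15, seed = 1L) {
  params <- params %||% cohort_params(seed = seed)
  params$n_lesions <- as.integer(n_analyzable + n_non_bcc + n_incomplete)
  params$seed <- as.integer(seed)
  cohort <- make_cohort(params)
  long <- make_cohort_series(cohort, background_sd_mm3 = background_sd_mm3,
                             seed = seed + 1L)
  ids <- unique(long$lesion_id)
  withr::with_seed(seed + 2L, {
    non_bcc_ids <- sample(ids, n_non_bcc)
    rest <- setdiff(ids, non_bcc_ids)
    incomplete_ids <- sample(rest, n_incomplete)
    drop_visit <- sample(paste0("V", 2:5), n_incomplete, replace = TRUE)
    non_bcc_labels <- sample(c("SCC", "fibrosis/scar"), n_non_bcc,
                             replace = TRUE)
  })
  lab <- setNames(non_bcc_labels, non_bcc_ids)
  sel <- long$lesion_id %in% non_bcc_ids
  long$subtype[sel] <- lab[long$lesion_id[sel]]
  drop <- tibble::tibble(lesion_id = incomplete_ids, visit = drop_visit)
  long <- dplyr::anti_join(long, drop, by = c("lesion_id", "visit"))
  keep <- !(ids %in% c(non_bcc_ids, incomplete_ids))
  list(
    table = long,
    truth = cohort[cohort$lesion_id %in% ids[keep], , drop = FALSE]
  )
}
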