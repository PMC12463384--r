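# Size-threshold prediction of PDT response and the depth correlation.

make_records <- function(values, actual, subtype = NULL) {
  out <- tibble::tibble(
    lesion_id = sprintf("L%02d", seq_along(values)),
    avht_v1_mm = values,
    actual_responder = actual
  )
  if (!is.null(subtype)) out$subtype <- subtype
  out
}

test_that("confusion counts match a brute-force enumeration", {
  rec <- make_records(c(0.05, 0.1, 0.12, 0.2, 0.3, 0.14, 0.16, 0.4, 0.08, 0.5),
                      c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
                        TRUE, FALSE))
  thr <- 0.15
  cm <- confusion_at_threshold(rec, "avht_v1_mm", thr)
  # exhaustive per-record enumeration
  tp <- fn <- tn <- fp <- 0
  for (i in seq_len(nrow(rec))) {
    pred <- rec$avht_v1_mm[i] <= thr
    if (pred && rec$actual_responder[i]) tp <- tp + 1
    if (!pred && rec$actual_responder[i]) fn <- fn + 1
    if (!pred && !rec$actual_responder[i]) tn <- tn + 1
    if (pred && !rec$actual_responder[i]) fp <- fp + 1
  }
  expect_equal(unlist(cm[1, c("tp", "fn", "tn", "fp")]),
               c(tp = tp, fn = fn, tn = tn, fp = fp))
  expect_equal(cm$tp + cm$fn, sum(rec$actual_responder))
  expect_equal(cm$tn + cm$fp, sum(!rec$actual_responder))

  # perfect separation
  sep <- make_records(c(0.1, 0.1, 0.3, 0.3), c(TRUE, TRUE, FALSE, FALSE))
  cs <- confusion_at_threshold(sep, "avht_v1_mm", 0.2)
  expect_equal(c(cs$fp, cs$fn), c(0, 0))

  # ties at the threshold count as predicted responders
  tie <- make_records(c(0.15, 0.15), c(TRUE, FALSE))
  ct <- confusion_at_threshold(tie, "avht_v1_mm", 0.15)
  expect_equal(c(ct$tp, ct$fp), c(1, 1))

  rec$avht_v1_mm[3] <- NA
  expect_error(confusion_at_threshold(rec, "avht_v1_mm", 0.15), "L03")
})

test_that("sens_spec computes the standard rates and errors on empty classes", {
  ss <- sens_spec(list(tp = 9, fn = 1, tn = 5, fp = 5))
  expect_equal(c(ss$sensitivity, ss$specificity), c(0.9, 0.5))
  expect_equal(unlist(sens_spec(list(tp = 4, fn = 0, tn = 6, fp = 0))),
               c(sensitivity = 1, specificity = 1))
  expect_error(sens_spec(list(tp = 0, fn = 0, tn = 5, fp = 5)), "responders")

  # complements: miss rate and false-positive rate
  expect_equal(ss$sensitivity + 1 / (9 + 1), 1)
  expect_equal(ss$specificity + 5 / (5 + 5), 1)
})

test_that("operational threshold sweep is self-consistent and monotone", {
  withr::with_seed(6, {
    x <- runif(60, 0, 0.4)
    rec <- make_records(x, runif(60) < plogis((0.15 - x) / 0.05))
  })
  ta <- operational_threshold(rec, "avht_v1_mm")

  # every sweep row equals a confusion_at_threshold recomputation
  for (i in seq(1, nrow(ta$sweep), by = 7)) {
    cm <- confusion_at_threshold(rec, "avht_v1_mm", ta$sweep$threshold[i])
    ss <- sens_spec(cm)
    expect_equal(ta$sweep$sensitivity[i], ss$sensitivity)
    expect_equal(ta$sweep$specificity[i], ss$specificity)
  }

  # monotone: sens non-decreasing, spec non-increasing in the threshold
  expect_true(all(diff(ta$sweep$sensitivity) >= 0))
  expect_true(all(diff(ta$sweep$specificity) <= 0))

  # two-record case: smallest candidate with sens = spec = 1 is returned
  two <- make_records(c(0.1, 0.3), c(TRUE, FALSE))
  t2 <- operational_threshold(two, "avht_v1_mm")
  expect_equal(t2$operational_threshold, 0.1)
  expect_equal(c(t2$sens_at_operational, t2$spec_at_operational), c(1, 1))

  expect_error(operational_threshold(make_records(1:3 / 10, rep(TRUE, 3)),
                                     "avht_v1_mm"),
               "responders and nonresponders")
})

test_that("planted logistic cohorts recover the 0.15 mm midpoint", {
  co <- make_cohort(cohort_params(n_lesions = 500, seed = 31))
  ta <- operational_threshold(co, "avht_v1_mm")
  expect_lt(abs(ta$operational_threshold - 0.15), 0.03)
})

test_that("exclude_aggressive filters micronodular and infiltrative only", {
  rec <- make_records(runif(20, 0, 0.4), rep(c(TRUE, FALSE), 10),
                      subtype = rep(c("superficial", "nodular",
                                      "micronodular", "infiltrative",
                                      "other"), 4))
  out <- suppressMessages(exclude_aggressive(rec))
  expect_equal(nrow(out), 12)
  expect_equal(attr(out, "n_removed"), 8)
  expect_false(any(out$subtype %in% c("micronodular", "infiltrative")))
  # original untouched
  expect_equal(nrow(rec), 20)

  benign <- rec[rec$subtype %in% c("superficial", "nodular"), ]
  expect_equal(nrow(suppressMessages(exclude_aggressive(benign))),
               nrow(benign))

  allagg <- rec[rec$subtype %in% c("micronodular", "infiltrative"), ]
  expect_warning(suppressMessages(exclude_aggressive(allagg)), "empty")

  rec$subtype[1] <- "SCC"
  expect_error(suppressMessages(exclude_aggressive(rec)), "Unknown subtype")
})

test_that("excluding planted thin aggressive nonresponders raises specificity", {
  co <- make_cohort(cohort_params(n_lesions = 400, aggressive_thin = TRUE,
                                  seed = 12))
  cm_all <- confusion_at_threshold(co, "avht_v1_mm", 0.15)
  ss_all <- sens_spec(cm_all)
  kept <- suppressMessages(exclude_aggressive(co))
  ss_kept <- sens_spec(confusion_at_threshold(kept, "avht_v1_mm", 0.15))
  expect_gt(ss_kept$specificity, ss_all$specificity)
})

test_that("depth correlation matches its OLS oracle", {
  # exact proportionality
  d <- tibble::tibble(depth_mm = seq(0.5, 3, length.out = 10))
  d$avht_mm <- 0.15 * d$depth_mm
  dc <- depth_correlation(d)
  expect_equal(c(dc$slope, dc$pearson_r, dc$ratio_summary),
               c(0.15, 1, 0.15), tolerance = 1e-9)

  # noisy pairs at the study's n = 15
  withr::with_seed(44, {
    depth <- runif(15, 0.3, 3)
    avht <- 0.15 * depth + rnorm(15, 0, 0.02)
  })
  dn <- depth_correlation(tibble::tibble(avht_mm = avht, depth_mm = depth))
  expect_lt(abs(dn$slope - 0.15), 0.05)
  oracle <- unname(coef(lm(avht ~ depth)))
  expect_equal(c(dn$intercept, dn$slope), oracle, tolerance = 1e-12)
  expect_lte(abs(dn$pearson_r), 1)

  expect_error(depth_correlation(d[1:2, ]), "at least 3")
  flat <- tibble::tibble(avht_mm = c(0.1, 0.2, 0.3), depth_mm = c(1, 1, 1))
  expect_error(depth_correlation(flat), "Zero-variance")
})
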