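test_that("flat QC series leaves the table unchanged", {
  plan <- tiny_plan(list(`1` = c("QC", rep("study", 4), "QC")))
  vals <- c(1000, 800, 900, 1100, 950, 1000)
  tbl <- tiny_intensities(plan, vals)
  out <- loess_drift_correct(tbl, plan, span = 1)
  expect_equal(out$intensity, vals, tolerance = 1e-10)
})

test_that("a linear QC trend is flattened to <1% relative SD at full span", {
  # QCs every other injection, drifting exactly linearly 1000 -> 2000
  types <- rep(c("QC", "study"), 5)
  types <- c(types, "QC")
  plan <- tiny_plan(list(`1` = types))
  qc_rows <- which(plan$sample_type == "QC")
  vals <- 1000 + 100 * (plan$run_order - 1)
  tbl <- tiny_intensities(plan, vals)
  out <- loess_drift_correct(tbl, plan, span = 1)
  qc_after <- out$intensity[qc_rows]
  expect_lt(sd(qc_after) / mean(qc_after), 0.01)
  # hand-fit line check: the fitted curve is the trend itself, so corrected
  # QCs all equal the weekly QC median
  expect_equal(qc_after, rep(median(vals[qc_rows]), length(qc_rows)), tolerance = 1e-6)
})

test_that("drift correction reduces QC RSD on drift-planted tables and preserves medians", {
  cohort <- generate_cohort(small_config(seed = 21, n_metab = 20, drift = 0.3, censor = 0))
  before <- qc_rsd(cohort$intensities, cohort$plan)
  corrected <- loess_drift_correct(cohort$intensities, cohort$plan)
  after <- qc_rsd(corrected, cohort$plan)
  j <- dplyr::inner_join(before, after, by = "metabolite", suffix = c("_pre", "_post"))
  expect_gte(mean(j$qc_rsd_post < j$qc_rsd_pre), 0.95)

  # unit preservation: weekly QC medians unchanged by the correction
  med <- function(tbl) {
    dplyr::left_join(tbl, cohort$plan, by = "injection_id") |>
      dplyr::filter(sample_type == "QC") |>
      dplyr::group_by(metabolite, week) |>
      dplyr::summarise(m = median(intensity), .groups = "drop")
  }
  expect_equal(med(corrected)$m, med(cohort$intensities)$m, tolerance = 0.02)
})

test_that("drift correction rejects weeks without QC anchors and keeps NAs missing", {
  plan <- tiny_plan(list(`1` = c("QC", "study", "study")))
  tbl <- tiny_intensities(plan, c(100, 110, NA))
  expect_error(loess_drift_correct(tbl, plan), "week")

  plan2 <- tiny_plan(list(`1` = c("QC", "study", "study", "QC")))
  tbl2 <- tiny_intensities(plan2, c(100, 110, NA, 120))
  out <- loess_drift_correct(tbl2, plan2)
  expect_true(is.na(out$intensity[3]))
  expect_equal(sum(is.na(out$intensity)), 1)

  # all-missing QC series: metabolite passes through with a warning
  tbl3 <- tiny_intensities(plan2, c(NA, 110, 115, NA))
  expect_warning(out3 <- loess_drift_correct(tbl3, plan2), "skipped")
  expect_equal(out3$intensity, tbl3$intensity)
})

test_that("weekly QC normalization divides by the weekly median", {
  plan <- tiny_plan(list(
    `1` = c("QC", "study", "QC"),
    `2` = c("QC", "study", "QC")
  ))
  # week 1 QC median 500, week 2 QC median 1000; identical underlying samples
  tbl <- tiny_intensities(plan, c(400, 1000, 600, 800, 2000, 1200))
  out <- weekly_qc_normalize(tbl, plan)
  expect_equal(out$intensity[2], 1000 / 500)
  expect_equal(out$intensity[5], 2000 / 1000)
  # identical underlying samples in weeks with different QC medians
  # normalize to equal values
  expect_equal(out$intensity[4:6], out$intensity[1:3])

  # zero weekly median is an error
  tbl0 <- tiny_intensities(plan, c(0, 10, 0, 800, 2000, 1200))
  expect_error(weekly_qc_normalize(tbl0, plan), "zero")
})

test_that("the missingness filter boundary is inclusive at 90%", {
  plan <- tiny_plan(list(`1` = c("QC", rep("study", 10), "QC")))
  present_9 <- c(100, rep(100, 9), NA, 100) # 9/10 study present
  present_10 <- c(100, rep(100, 10), 100)
  tbl <- dplyr::bind_rows(
    tiny_intensities(plan, present_9, "at_90"),
    tiny_intensities(plan, present_10, "full"),
    tiny_intensities(plan, c(100, rep(c(100, NA), 5), 100), "at_50")
  )
  res <- filter_metabolites(tbl, plan, min_nonmissing = 0.90)
  expect_setequal(unique(res$intensities$metabolite), c("at_90", "full"))
  expect_equal(res$report$n_input, 3)
  expect_equal(res$report$n_retained, 2)

  # 89.9% is dropped: 899 of 1000 present
  big_plan <- tiny_plan(list(`1` = c("QC", rep("study", 1000), "QC")))
  v <- c(100, rep(100, 1000), 100)
  v[1 + (900:1000)] <- NA # 899 present among study
  res2 <- filter_metabolites(tiny_intensities(big_plan, v), big_plan, 0.90)
  expect_equal(res2$report$n_retained, 0)
})

test_that("filter is idempotent and commutes with normalization", {
  # censoring fractions straddle the threshold so some metabolites drop
  specs <- purrr::map2(
    sprintf("m%02d", 1:6), c(0, 0.05, 0.08, 0.2, 0.3, 0.4),
    function(nm, cq) metabolite_spec(nm, base_log2 = 13, censor_quantile = cq,
                                     drift_amplitude = 0.2)
  )
  cohort <- generate_cohort(cohort_config(
    group_sizes = c(iNPH = 24, AD = 20), metabolite_specs = specs,
    n_weeks = 2, qc_interval = 5, seed = 8
  ))
  norm <- suppressWarnings(weekly_qc_normalize(
    loess_drift_correct(cohort$intensities, cohort$plan), cohort$plan
  ))
  f1 <- filter_metabolites(norm, cohort$plan, 0.85)
  expect_gt(f1$report$n_retained, 0)
  expect_lt(f1$report$n_retained, 6)
  f2 <- filter_metabolites(f1$intensities, cohort$plan, 0.85)
  expect_identical(f1$intensities, f2$intensities)
  expect_equal(f2$report$n_input, f2$report$n_retained)

  # filter-then-normalize equals normalize-then-filter
  fn <- suppressWarnings(weekly_qc_normalize(
    filter_metabolites(
      loess_drift_correct(cohort$intensities, cohort$plan), cohort$plan, 0.85
    )$intensities,
    cohort$plan
  ))
  nf <- f1$intensities
  expect_equal(
    dplyr::arrange(fn, metabolite, injection_id)$intensity,
    dplyr::arrange(nf, metabolite, injection_id)$intensity
  )
})

test_that("the default panel yields 59 of 219 retained metabolites", {
  cohort <- generate_cohort(cohort_config(seed = 4))
  norm <- suppressWarnings(weekly_qc_normalize(
    loess_drift_correct(cohort$intensities, cohort$plan), cohort$plan
  ))
  res <- filter_metabolites(norm, cohort$plan)
  expect_equal(res$report$n_input, 219)
  expect_equal(res$report$n_retained, 59)
  expect_equal(round(100 * glance(res$report)$frac_retained, 1), 26.9)
  # the eight signature metabolites are all retained
  expect_true(all(inph_signature_profiles()$metabolite %in%
    res$intensities$metabolite))
})

test_that("half-minimum imputation fills exactly the missing cells", {
  plan <- tiny_plan(list(`1` = c("QC", rep("study", 4), "QC")))
  tbl <- tiny_intensities(plan, c(50, 10, NA, 40, NA, 60))
  out <- impute_missing(tbl, "half_min")
  expect_equal(out$intensity, c(50, 10, 5, 40, 5, 60))
  expect_identical(impute_missing(tbl, "none"), tbl)
  # identity when nothing is missing
  full <- tiny_intensities(plan, c(50, 10, 20, 40, 30, 60))
  expect_equal(impute_missing(full, "half_min")$intensity, full$intensity)
  # all-missing metabolite cannot be imputed
  gone <- tiny_intensities(plan, rep(NA_real_, 6), "gone")
  expect_error(impute_missing(gone, "half_min"), "no present values")
})

test_that("log2 transform rejects non-positive intensities", {
  plan <- tiny_plan(list(`1` = c("QC", "study", "QC")))
  expect_error(transform_log2(tiny_intensities(plan, c(1, 0, 4))), "positive")
  out <- transform_log2(tiny_intensities(plan, c(1, 2, 4)))
  expect_equal(out$intensity, c(0, 1, 2))
})
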