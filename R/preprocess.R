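# QC-anchored preprocessing of LC-MS relative intensities. All operations
# take and return the long intensity tibble (metabolite, injection_id,
# intensity) and never turn a present value into a missing one, so the
# missingness filter commutes with normalization.

join_plan <- function(intensities, plan) {
  out <- left_join(intensities, plan, by = "injection_id")
  if (anyNA(out$week)) abort("some injection ids are absent from the plan.")
  out
}

check_qc_weeks <- function(plan) {
  qc <- plan %>%
    group_by(.data$week) %>%
    summarise(n_qc = sum(.data$sample_type == "QC"), .groups = "drop")
  bad <- qc$week[qc$n_qc < 2]
  if (length(bad)) {
    abort(sprintf(
      "week(s) %s have fewer than 2 QC injections; drift correction needs QC anchors.",
      paste(bad, collapse = ", ")
    ))
  }
}

#' Correct within-week signal drift using pooled-QC LOESS curves
#'
#' For every metabolite and weekly batch, a degree-1 LOESS curve is fitted
#' to the QC intensities against run order (a straight line is used when a
#' week holds fewer than four usable QC points). The fitted curve is
#' evaluated at every injection's run order by linear interpolation (and
#' linear extrapolation beyond the outermost QC), each intensity is divided
#' by the curve, and the result is rescaled by that week's median QC
#' intensity so units are preserved. Correction factors are clamped to
#' `[0.2, 5]` to guard against extrapolation blow-ups at batch edges.
#' Missing values stay missing. Metabolite-weeks with fewer than two
#' present QC values are passed through unchanged with a warning.
#'
#' @param intensities Long intensity tibble (`metabolite`, `injection_id`,
#'   `intensity`).
#' @param plan Injection plan, see [make_injection_plan()]. Every week must
#'   contain at least two QC injections.
#' @param span LOESS span on the QC points, in `(0, 1]`.
#' @return Drift-corrected intensity tibble, same rows and order.
#' @export
loess_drift_correct <- function(intensities, plan, span = 0.75) {
  assert_scalar_number(span, "span", lower = 1e-6, upper = 1)
  check_qc_weeks(plan)
  df <- join_plan(intensities, plan)
  skipped <- character()
  out <- df %>%
    group_by(.data$metabolite, .data$week) %>%
    group_modify(function(d, key) {
      qc <- d$sample_type == "QC" & !is.na(d$intensity)
      if (sum(qc) < 2) {
        skipped <<- c(skipped, key$metabolite)
        return(d)
      }
      x <- d$run_order[qc]
      y <- d$intensity[qc]
      fitted <- if (sum(qc) < 4) {
        unname(predict(lm(y ~ x), newdata = data.frame(x = x)))
      } else {
        suppressWarnings({
          fit <- loess(y ~ x, span = span, degree = 1,
                       control = loess.control(surface = "direct"))
          unname(predict(fit, newdata = data.frame(x = x)))
        })
      }
      curve <- approx_extrap(x, fitted, d$run_order)
      f <- curve / median(y)
      f <- pmin(5, pmax(0.2, f))
      d$intensity <- d$intensity / f
      d
    }) %>%
    ungroup()
  if (length(skipped)) {
    warn(sprintf(
      "drift correction skipped for %d metabolite-week(s) with < 2 present QC values (e.g. %s).",
      length(skipped), skipped[1]
    ))
  }
  out %>%
    select("metabolite", "injection_id", "intensity") %>%
    semi_reorder(intensities)
}

# linear interpolation inside the QC range, linear extrapolation outside
approx_extrap <- function(x, y, xout) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (length(x) == 1L) return(rep(y, length(xout)))
  res <- approx(x, y, xout = xout, ties = mean)$y
  lo <- xout < min(x)
  hi <- xout > max(x)
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    res[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    n <- length(x)
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    res[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  res
}

# restore the row order of `template` after grouped operations
semi_reorder <- function(df, template) {
  key <- paste(template$metabolite, template$injection_id)
  df[match(key, paste(df$metabolite, df$injection_id)), ]
}

#' Normalize inter-week effects by the weekly median QC intensity
#'
#' Each intensity is divided by the median pooled-QC intensity of the same
#' metabolite in the same week. Metabolite-weeks without any present QC
#' value are passed through unchanged with a warning; a zero weekly QC
#' median is an error.
#'
#' @inheritParams loess_drift_correct
#' @return Normalized intensity tibble (unitless ratios to the weekly QC).
#' @export
weekly_qc_normalize <- function(intensities, plan) {
  df <- join_plan(intensities, plan)
  med <- df %>%
    filter(.data$sample_type == "QC") %>%
    group_by(.data$metabolite, .data$week) %>%
    summarise(qc_median = median(.data$intensity, na.rm = TRUE), .groups = "drop")
  if (any(!is.na(med$qc_median) & med$qc_median == 0)) {
    bad <- med[!is.na(med$qc_median) & med$qc_median == 0, ]
    abort(sprintf(
      "weekly QC median is zero for metabolite '%s' in week %d.",
      bad$metabolite[1], bad$week[1]
    ))
  }
  if (anyNA(med$qc_median)) {
    warn(sprintf(
      "%d metabolite-week(s) have no present QC value; passed through unnormalized.",
      sum(is.na(med$qc_median))
    ))
  }
  df %>%
    left_join(med, by = c("metabolite", "week")) %>%
    mutate(intensity = ifelse(is.na(.data$qc_median),
      .data$intensity, .data$intensity / .data$qc_median
    )) %>%
    select("metabolite", "injection_id", "intensity")
}

#' Filter metabolites by non-missing fraction among study samples
#'
#' Retains metabolites whose fraction of non-missing values across study
#' injections (QCs and blanks excluded) is at least `min_nonmissing`; the
#' boundary is inclusive, so a metabolite present in exactly 90 percent of
#' study samples passes the default filter.
#'
#' @inheritParams loess_drift_correct
#' @param min_nonmissing Minimum non-missing fraction, default 0.90.
#' @return A list with `intensities` (the filtered table) and `report`, a
#'   `qc_report` holding per-metabolite non-missing fractions and the
#'   input/retained counts.
#' @export
filter_metabolites <- function(intensities, plan, min_nonmissing = 0.90) {
  assert_scalar_number(min_nonmissing, "min_nonmissing", 0, 1)
  df <- join_plan(intensities, plan)
  per <- df %>%
    filter(.data$sample_type == "study") %>%
    group_by(.data$metabolite) %>%
    summarise(frac_nonmissing = mean(!is.na(.data$intensity)), .groups = "drop") %>%
    mutate(retained = .data$frac_nonmissing >= min_nonmissing - 1e-9)
  kept <- per$metabolite[per$retained]
  report <- structure(
    list(
      metabolites = per,
      n_input = nrow(per),
      n_retained = length(kept),
      min_nonmissing = min_nonmissing
    ),
    class = "qc_report"
  )
  list(
    intensities = filter(intensities, .data$metabolite %in% kept),
    report = report
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d of %d metabolites retained (%.1f%%) at >= %.0f%% non-missing\n",
    x$n_retained, x$n_input, 100 * x$n_retained / x$n_input,
    100 * x$min_nonmissing
  ))
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) x$metabolites

#' @export
glance.qc_report <- function(x, ...) {
  tibble(
    n_input = x$n_input, n_retained = x$n_retained,
    frac_retained = x$n_retained / x$n_input,
    min_nonmissing = x$min_nonmissing
  )
}

#' Impute missing intensities
#'
#' `"half_min"` replaces each missing cell with half the metabolite's
#' minimum present value (a standard proxy for below-detection-limit
#' values); `"none"` passes the table through. Imputation feeds only the
#' multivariate models; univariate statistics use complete cases.
#'
#' @inheritParams loess_drift_correct
#' @param strategy `"half_min"` or `"none"`.
#' @return Intensity tibble with no missing cells (under `"half_min"`).
#' @export
impute_missing <- function(intensities, strategy = c("half_min", "none")) {
  strategy <- match.arg(strategy)
  if (strategy == "none") return(intensities)
  intensities %>%
    group_by(.data$metabolite) %>%
    group_modify(function(d, key) {
      if (all(is.na(d$intensity))) {
        abort(sprintf("metabolite '%s' has no present values to impute from.", key$metabolite))
      }
      fill <- min(d$intensity, na.rm = TRUE) / 2
      d$intensity[is.na(d$intensity)] <- fill
      d
    }) %>%
    ungroup() %>%
    select("metabolite", "injection_id", "intensity")
}

#' Per-metabolite QC relative standard deviation
#'
#' Mean over weekly batches of the within-week coefficient of variation
#' (sd/mean) of pooled-QC intensities. Inter-week level differences are
#' deliberately excluded: they are the target of [weekly_qc_normalize()],
#' not of the drift correction whose effect this statistic measures.
#'
#' @inheritParams loess_drift_correct
#' @return Tibble with `metabolite` and `qc_rsd`.
#' @export
qc_rsd <- function(intensities, plan) {
  join_plan(intensities, plan) %>%
    filter(.data$sample_type == "QC", !is.na(.data$intensity)) %>%
    group_by(.data$metabolite, .data$week) %>%
    summarise(cv = sd(.data$intensity) / mean(.data$intensity), .groups = "drop") %>%
    group_by(.data$metabolite) %>%
    summarise(qc_rsd = mean(.data$cv, na.rm = TRUE), .groups = "drop")
}

#' Log2-transform an intensity table
#'
#' Downstream statistics operate on log2 normalized intensities (group
#' contrasts are then log2 fold changes with symmetric confidence
#' intervals). Non-positive present values are rejected.
#'
#' @inheritParams loess_drift_correct
#' @return Intensity tibble on the log2 scale.
#' @export
transform_log2 <- function(intensities) {
  if (any(intensities$intensity <= 0, na.rm = TRUE)) {
    abort("intensities must be positive to log2-transform.")
  }
  mutate(intensities, intensity = log2(.data$intensity))
}

#' Run the full preprocessing contract
#'
#' Convenience wrapper: drift correction, weekly QC normalization,
#' missingness filtering, and log2 transformation, with optional
#' half-minimum imputation for the multivariate stages.
#'
#' @inheritParams loess_drift_correct
#' @inheritParams filter_metabolites
#' @param impute Imputation strategy for the returned `imputed` table.
#' @return List with `log2` (complete-case log2 table for univariate
#'   statistics), `imputed` (imputed log2 table for multivariate models),
#'   and `report` (the [filter_metabolites()] `qc_report`).
#' @export
preprocess_intensities <- function(intensities, plan, span = 0.75,
                                   min_nonmissing = 0.90,
                                   impute = c("half_min", "none")) {
  impute <- match.arg(impute)
  corrected <- loess_drift_correct(intensities, plan, span = span)
  normalized <- weekly_qc_normalize(corrected, plan)
  filtered <- filter_metabolites(normalized, plan, min_nonmissing = min_nonmissing)
  log2_tbl <- transform_log2(filtered$intensities)
  list(
    log2 = log2_tbl,
    imputed = transform_log2(impute_missing(filtered$intensities, impute)),
    report = filtered$report
  )
}
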