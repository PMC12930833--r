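#' Build an LC-MS injection plan with interleaved pooled-QC injections
#'
#' Study samples are randomly permuted and split across weekly analytical
#' batches. Within each week the sequence opens with a pooled-QC injection,
#' a QC is injected after every `qc_interval` study samples, and the week
#' closes with a QC, so every week carries at least two QC injections and
#' drift can be anchored at both batch edges.
#'
#' @param samples Character vector of study sample ids, or a single integer
#'   count (ids `S001`, `S002`, ... are generated).
#' @param n_weeks Number of weekly batches; at most the number of samples.
#' @param qc_interval Study injections between QCs; at least 2.
#' @param seed Seed for the random permutation of samples across weeks.
#' @return A tibble with columns `injection_id`, `sample_id` (NA for QC),
#'   `week`, `run_order` (1-based, gapless within week), and `sample_type`
#'   (`"study"` or `"QC"`).
#' @export
#' @examples
#' make_injection_plan(10, n_weeks = 1, qc_interval = 5, seed = 1)
make_injection_plan <- function(samples, n_weeks = 1, qc_interval = 8, seed = 1) {
  if (is.numeric(samples) && length(samples) == 1L) {
    samples <- sprintf("S%03d", seq_len(samples))
  }
  n_study <- length(samples)
  if (n_study < n_weeks) abort("need at least one study sample per week.")
  if (qc_interval < 2) abort("`qc_interval` must be >= 2.")
  perm <- with_seed(seed, sample(samples))
  week_of <- sort(rep_len(seq_len(n_weeks), n_study))
  purrr::map_dfr(seq_len(n_weeks), function(w) {
    ids <- perm[week_of == w]
    type <- c("QC")
    sid <- c(NA_character_)
    for (i in seq_along(ids)) {
      type <- c(type, "study")
      sid <- c(sid, ids[i])
      if (i %% qc_interval == 0) {
        type <- c(type, "QC")
        sid <- c(sid, NA_character_)
      }
    }
    type <- c(type, "QC")
    sid <- c(sid, NA_character_)
    tibble(
      injection_id = sprintf("w%02d_i%03d", w, seq_along(type)),
      sample_id = sid,
      week = w,
      run_order = seq_along(type),
      sample_type = type
    )
  })
}

# Draw subject demographics and CSF biomarkers for one group. Ages are
# discrete-uniform on the group's interquartile range widened by +/-6 years
# (only medians and quartiles are reported for the emulated cohort);
# biomarkers are log-normal with the reported median and sigma chosen so the
# quartiles approximately match.
draw_group_subjects <- function(group, n, dem) {
  row <- dem[dem$group == group, ]
  ages <- sample(seq(max(40, row$age_q1 - 6), min(100, row$age_q3 + 6)), n, replace = TRUE)
  sex <- ifelse(runif(n) < row$frac_female, "F", "M")
  lnorm_par <- function(med, q1, q3) {
    c(meanlog = log(med), sdlog = log(q3 / q1) / (2 * qnorm(0.75)))
  }
  ab <- lnorm_par(row$abeta42_med, row$abeta42_q1, row$abeta42_q3)
  ta <- lnorm_par(row$tau_med, row$tau_q1, row$tau_q3)
  pt <- lnorm_par(row$ptau_med, row$ptau_q1, row$ptau_q3)
  tibble(
    group = group,
    age = as.integer(ages),
    sex = sex,
    abeta42 = rlnorm(n, ab["meanlog"], ab["sdlog"]),
    tau = rlnorm(n, ta["meanlog"], ta["sdlog"]),
    ptau = rlnorm(n, pt["meanlog"], pt["sdlog"])
  )
}

#' Generate a seeded synthetic CSF metabolomics cohort
#'
#' Produces subjects, an injection plan, and a raw intensity table carrying
#' the statistical structure the downstream pipeline assumes: per-group
#' demographic and biomarker distributions, planted group effects on the
#' log2 scale, shared weekly batch offsets, smooth monotone within-week
#' signal drift affecting study and QC injections alike, analytical noise on
#' pooled-QC injections, and left-censored (detection-limit) missingness.
#'
#' Cortical biopsy AD status is assigned to a random 66.7 percent of iNPH
#' subjects, 73 percent of whom are AD-positive, independently of metabolite
#' values; Evans index and MR ventricular volume are drawn for iNPH subjects
#' only, independent of the metabolome.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `subjects`,
#'   `plan` (see [make_injection_plan()]), and `intensities` (long tibble:
#'   `metabolite`, `injection_id`, `intensity`; NA marks censored cells).
#' @export
#' @examples
#' cfg <- cohort_config(
#'   group_sizes = c(iNPH = 12, AD = 10),
#'   metabolite_specs = list(metabolite_spec("m1")),
#'   n_weeks = 2, seed = 7
#' )
#' cohort <- generate_cohort(cfg)
#' dplyr::count(cohort$subjects, group)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config.")
  seeds <- derive_seeds(config$seed, 3)
  dem <- group_demographics()
  sizes <- config$group_sizes[config$group_sizes > 0]

  subjects <- with_seed(seeds[1], {
    subj <- purrr::map_dfr(names(sizes), function(g) {
      draw_group_subjects(g, sizes[[g]], dem)
    })
    subj$id <- sprintf("S%03d", seq_len(nrow(subj)))
    subj$evans_index <- NA_real_
    subj$ventricular_volume <- NA_real_
    subj$biopsy_ad <- "none"
    is_inph <- subj$group == "iNPH"
    n_inph <- sum(is_inph)
    if (n_inph > 0) {
      subj$evans_index[is_inph] <- pmax(0.31, rnorm(n_inph, 0.36, 0.03))
      has_mri <- is_inph & runif(nrow(subj)) < 0.7
      subj$ventricular_volume[has_mri] <- rlnorm(sum(has_mri), log(130), 0.25)
      n_biopsy <- round(0.667 * n_inph)
      biopsied <- sample(which(is_inph), n_biopsy)
      ad_pos <- sample(biopsied, round(0.73 * n_biopsy))
      subj$biopsy_ad[biopsied] <- "ADneg"
      subj$biopsy_ad[ad_pos] <- "ADpos"
    }
    select(
      subj, "id", "group", "age", "sex", "abeta42", "tau", "ptau",
      "evans_index", "ventricular_volume", "biopsy_ad"
    )
  })

  plan <- make_injection_plan(
    subjects$id,
    n_weeks = config$n_weeks, qc_interval = config$qc_interval,
    seed = seeds[2]
  )

  intensities <- with_seed(seeds[3], {
    simulate_intensities(config$metabolite_specs, subjects, plan)
  })

  structure(
    list(subjects = subjects, plan = plan, intensities = intensities),
    class = "synthetic_cohort"
  )
}

# Simulate the raw intensity table for a list of metabolite specs. Drift is
# a monotone quadratic in run order, scaled to the spec's drift_amplitude
# with a random direction per week, applied multiplicatively to every
# injection in that week.
simulate_intensities <- function(specs, subjects, plan) {
  is_study <- plan$sample_type == "study"
  subj_row <- match(plan$sample_id, subjects$id)
  weeks <- sort(unique(plan$week))
  # normalized position of each injection within its week, in [0, 1]
  tpos <- unsplit(
    lapply(split(plan$run_order, plan$week), function(r) {
      if (length(r) == 1L) 0 else (r - min(r)) / (max(r) - min(r))
    }),
    plan$week
  )
  purrr::map_dfr(specs, function(sp) {
    subj_mu <- sp$base_log2 +
      sp$group_offsets[subjects$group] +
      sp$age_slope * (subjects$age - 70) +
      sp$sex_offset * (subjects$sex == "M")
    qc_mu <- mean(subj_mu)
    week_off <- setNames(rnorm(length(weeks), 0, sp$week_sd), weeks)
    dir <- setNames(sample(c(-1, 1), length(weeks), replace = TRUE), weeks)
    curv <- setNames(runif(length(weeks)), weeks)
    w <- as.character(plan$week)
    drift_factor <- 1 + sp$drift_amplitude * dir[w] *
      (curv[w] * tpos + (1 - curv[w]) * tpos^2)
    mu <- ifelse(is_study, subj_mu[subj_row], qc_mu)
    noise <- ifelse(is_study,
      rnorm(nrow(plan), 0, sp$subject_sd),
      rnorm(nrow(plan), 0, sp$qc_sd)
    )
    val <- 2^(mu + week_off[w] + noise) * drift_factor
    if (sp$censor_quantile > 0) {
      thr <- quantile(val[is_study], sp$censor_quantile, na.rm = TRUE)
      val[val < thr] <- NA_real_
    }
    tibble(metabolite = sp$name, injection_id = plan$injection_id, intensity = unname(val))
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d injections (%d QC), %d metabolites\n",
    nrow(x$subjects), nrow(x$plan), sum(x$plan$sample_type == "QC"),
    dplyr::n_distinct(x$intensities$metabolite)
  ))
  invisible(x)
}

#' Write / read a cohort as plain-text tables
#'
#' The on-disk dialect is TSV: an intensity table with metabolites as rows
#' and injection ids as columns, a sample sheet (`injection_id`,
#' `sample_id`, `week`, `run_order`, `sample_type`), and a subject table.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wide <- tidyr::pivot_wider(
    cohort$intensities,
    names_from = "injection_id", values_from = "intensity"
  )
  readr::write_tsv(wide, file.path(dir, "intensities.tsv"))
  readr::write_tsv(cohort$plan, file.path(dir, "sample_sheet.tsv"))
  readr::write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  wide <- readr::read_tsv(file.path(dir, "intensities.tsv"), show_col_types = FALSE)
  intensities <- tidyr::pivot_longer(
    wide, -"metabolite",
    names_to = "injection_id", values_to = "intensity"
  )
  structure(
    list(
      subjects = readr::read_tsv(file.path(dir, "subjects.tsv"), show_col_types = FALSE),
      plan = readr::read_tsv(file.path(dir, "sample_sheet.tsv"), show_col_types = FALSE),
      intensities = intensities
    ),
    class = "synthetic_cohort"
  )
}
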