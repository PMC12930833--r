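#' Diagnostic groups modelled by the cohort generator
#'
#' Six diagnostic groups: idiopathic normal pressure hydrocephalus (iNPH),
#' Alzheimer's disease (AD), AD-related mild cognitive impairment (ADMCI),
#' stable MCI, frontotemporal dementia (FTD), and neurologically healthy
#' controls.
#'
#' @return Character vector of group labels, iNPH first.
#' @export
cohort_groups <- function() {
  c("iNPH", "AD", "ADMCI", "MCI", "FTD", "Control")
}

# Per-group demographics and CSF biomarker summaries used by the generator:
# group size, age median and quartiles (years), fraction female, and
# median (Q1, Q3) of amyloid-beta42, total tau, and phosphorylated tau
# (all ng/L), matching the study cohort the simulator emulates.
group_demographics <- function() {
  tibble::tribble(
    ~group,    ~n,   ~age_q1, ~age_med, ~age_q3, ~frac_female,
    "iNPH",    120L, 70,      74,       78,      0.38,
    "AD",      72L,  66,      72,       76,      0.60,
    "ADMCI",   24L,  67,      71,       76,      0.54,
    "MCI",     48L,  61,      70,       74,      0.35,
    "FTD",     8L,   64,      71,       76,      0.38,
    "Control", 44L,  82,      88,       88,      0.23
  ) %>%
    left_join(
      tibble::tribble(
        ~group,    ~abeta42_med, ~abeta42_q1, ~abeta42_q3,
        ~tau_med, ~tau_q1, ~tau_q3, ~ptau_med, ~ptau_q1, ~ptau_q3,
        "iNPH",    586, 418, 680, 180, 139, 240, 26, 21, 32,
        "AD",      400, 340, 465, 680, 471, 920, 84, 60, 115,
        "ADMCI",   387, 350, 483, 528, 445, 650, 77, 55, 93,
        "MCI",     754, 645, 995, 244, 186, 330, 45, 35, 54,
        "FTD",     710, 595, 819, 265, 222, 460, 46, 35, 55,
        "Control", 663, 494, 927, 425, 353, 681, 64, 45, 78
      ),
      by = "group"
    )
}

#' Specify one simulated metabolite
#'
#' Describes the generative model of a single metabolite on the log2 scale:
#' `log2(intensity) = base_log2 + group_offset + age_slope * (age - 70) +
#' sex_offset * 1[male] + week offset + within-week drift + subject noise`,
#' exponentiated to the intensity scale and left-censored below the
#' `censor_quantile` of the study-sample distribution (detection-limit
#' dropout).
#'
#' @param name Metabolite name.
#' @param base_log2 Baseline log2 intensity for the iNPH reference group.
#' @param group_offsets Named numeric vector of log2 offsets per diagnostic
#'   group relative to iNPH (missing groups default to 0). The iNPH-vs-group
#'   log2 fold change implied is `-group_offsets[group]`.
#' @param age_slope Log2 units per year of age (centred at 70).
#' @param sex_offset Log2 offset for males.
#' @param subject_sd Between-subject SD, log2 units; must be positive.
#' @param week_sd SD of the shared weekly batch offset, log2 units.
#' @param drift_amplitude Within-week signal drift as a fraction of signal
#'   (0.3 = up to 30 percent monotone drift across a week).
#' @param censor_quantile Fraction of study intensities censored as missing
#'   from below; must be in `[0, 1)`.
#' @param qc_sd Analytical SD of pooled-QC injections, log2 units.
#' @return A `metabolite_spec` list.
#' @export
metabolite_spec <- function(name,
                            base_log2 = 15,
                            group_offsets = c(),
                            age_slope = 0,
                            sex_offset = 0,
                            subject_sd = 0.5,
                            week_sd = 0.15,
                            drift_amplitude = 0,
                            censor_quantile = 0,
                            qc_sd = 0.05) {
  if (subject_sd <= 0) abort("`subject_sd` must be > 0.")
  if (censor_quantile < 0 || censor_quantile >= 1) {
    abort("`censor_quantile` must be in [0, 1).")
  }
  offs <- setNames(rep(0, length(cohort_groups())), cohort_groups())
  if (length(group_offsets)) {
    bad <- setdiff(names(group_offsets), cohort_groups())
    if (length(bad)) abort(paste0("unknown group(s): ", paste(bad, collapse = ", ")))
    offs[names(group_offsets)] <- group_offsets
  }
  structure(
    list(
      name = name, base_log2 = base_log2, group_offsets = offs,
      age_slope = age_slope, sex_offset = sex_offset,
      subject_sd = subject_sd, week_sd = week_sd,
      drift_amplitude = drift_amplitude, censor_quantile = censor_quantile,
      qc_sd = qc_sd
    ),
    class = "metabolite_spec"
  )
}

#' Effect profiles of the iNPH discriminatory metabolite signature
#'
#' The eight metabolites consistently reduced in iNPH relative to every other
#' diagnostic group and controls (five amino acids plus isobutyrylcarnitine,
#' citric acid, and dehydroascorbic acid). `log2fc` columns are the
#' iNPH-minus-group log2 fold changes; `subject_sd` is the between-subject
#' noise calibrated so that a 120-vs-72 contrast reproduces the reported
#' iNPH-vs-AD 95 percent confidence-interval width
#' (`sd = width / (2 z_0.975) / sqrt(1/120 + 1/72)`).
#'
#' @return A tibble with one row per signature metabolite.
#' @export
inph_signature_profiles <- function() {
  prof <- tibble::tribble(
    ~metabolite,            ~AD,   ~ADMCI, ~MCI,  ~FTD,  ~Control, ~ci_width_ad,
    "isobutyrylcarnitine",  -0.48, -0.55,  -0.37, -1.12, -0.43,    0.42,
    "proline",              -0.40, -0.29,  -0.35, -0.59, -0.28,    0.30,
    "threonine",            -0.28, -0.32,  -0.17, -0.27, -0.21,    0.21,
    "histidine",            -0.24, -0.30,  -0.34, -0.28, -0.22,    0.23,
    "tyrosine",             -0.29, -0.31,  -0.42, -0.39, -0.27,    0.28,
    "tryptophan",           -0.31, -0.47,  -0.32, -0.46, -0.23,    0.29,
    "citric acid",          -0.21, -0.18,  -0.16, -0.33, -0.16,    0.18,
    "dehydroascorbic acid", -0.19, -0.18,  -0.15, -0.29, -0.16,    0.18
  )
  prof %>%
    mutate(
      subject_sd = .data$ci_width_ad / (2 * qnorm(0.975)) / sqrt(1 / 120 + 1 / 72)
    ) %>%
    select(-"ci_width_ad")
}

# Build a metabolite_spec from one signature profile row. Group offsets are
# minus the iNPH-vs-group log2FC (other groups sit above the iNPH baseline).
signature_spec <- function(row, ...) {
  groups <- c("AD", "ADMCI", "MCI", "FTD", "Control")
  metabolite_spec(
    name = row$metabolite,
    group_offsets = setNames(-as.numeric(row[groups]), groups),
    subject_sd = row$subject_sd,
    ...
  )
}

#' Default metabolite panel for the simulator
#'
#' A 219-metabolite candidate panel: the eight signature metabolites plus 51
#' well-detected null metabolites (low censoring, so 59 in total survive the
#' 90 percent non-missing filter) and 160 poorly detected null metabolites
#' whose left-censoring fractions span 0.15-0.50 and which the filter drops.
#'
#' @param n_total Total panel size.
#' @param n_detected Number of metabolites constructed to pass the
#'   missingness filter (includes the eight signature metabolites).
#' @param drift_amplitude Within-week drift fraction applied to every
#'   metabolite.
#' @param effect_scale Multiplier on the planted signature log2 fold changes
#'   (0 gives an all-null panel).
#' @param censor_detected Censoring fraction for the well-detected
#'   metabolites.
#' @param seed Seed for the baseline-intensity and noise-scale draws of the
#'   null metabolites.
#' @return List of [metabolite_spec()] objects.
#' @export
default_metabolite_specs <- function(n_total = 219,
                                     n_detected = 59,
                                     drift_amplitude = 0.3,
                                     effect_scale = 1,
                                     censor_detected = 0.05,
                                     seed = 20260926) {
  prof <- inph_signature_profiles()
  n_sig <- nrow(prof)
  if (n_detected < n_sig || n_total < n_detected) {
    abort("need n_total >= n_detected >= number of signature metabolites.")
  }
  with_seed(seed, {
    base <- runif(n_total, 10, 20)
    sds <- runif(n_total, 0.3, 0.8)
    sig <- purrr::map(seq_len(n_sig), function(i) {
      row <- prof[i, ]
      row[c("AD", "ADMCI", "MCI", "FTD", "Control")] <-
        row[c("AD", "ADMCI", "MCI", "FTD", "Control")] * effect_scale
      signature_spec(
        row,
        base_log2 = base[i],
        drift_amplitude = drift_amplitude,
        censor_quantile = censor_detected
      )
    })
    n_null_pass <- n_detected - n_sig
    n_fail <- n_total - n_detected
    censor_fail <- seq(0.15, 0.50, length.out = max(n_fail, 1L))
    nulls <- purrr::map(seq_len(n_total - n_sig), function(j) {
      i <- n_sig + j
      metabolite_spec(
        name = sprintf("M%03d", i),
        base_log2 = base[i],
        subject_sd = sds[i],
        drift_amplitude = drift_amplitude,
        censor_quantile = if (j <= n_null_pass) censor_detected else censor_fail[j - n_null_pass]
      )
    })
    c(sig, nulls)
  })
}

#' Configure a synthetic cohort
#'
#' @param group_sizes Named integer vector of subjects per diagnostic group;
#'   defaults to the study sizes (120 iNPH, 72 AD, 24 ADMCI, 48 MCI, 8 FTD,
#'   44 controls). Groups may be omitted or set to 0.
#' @param metabolite_specs List of [metabolite_spec()] objects; defaults to
#'   the 219-metabolite panel of [default_metabolite_specs()].
#' @param n_weeks Number of weekly analytical batches.
#' @param qc_interval Number of study injections between pooled-QC
#'   injections within a week; must be at least 2.
#' @param seed Master seed; all randomness in [generate_cohort()] flows from
#'   it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = NULL,
                          metabolite_specs = NULL,
                          n_weeks = 8,
                          qc_interval = 8,
                          seed = 1) {
  sizes <- setNames(rep(0L, length(cohort_groups())), cohort_groups())
  if (is.null(group_sizes)) {
    dem <- group_demographics()
    sizes[dem$group] <- dem$n
  } else {
    bad <- setdiff(names(group_sizes), cohort_groups())
    if (length(bad)) abort(paste0("unknown group(s): ", paste(bad, collapse = ", ")))
    if (any(group_sizes < 0)) abort("group sizes must be >= 0.")
    sizes[names(group_sizes)] <- as.integer(group_sizes)
  }
  if (sum(sizes) == 0L) abort("at least one group must have a positive size.")
  if (qc_interval < 2) abort("`qc_interval` must be >= 2.")
  if (n_weeks < 1) abort("`n_weeks` must be >= 1.")
  if (is.null(metabolite_specs)) metabolite_specs <- default_metabolite_specs()
  if (!length(metabolite_specs)) abort("need at least one metabolite spec.")
  structure(
    list(
      group_sizes = sizes,
      metabolite_specs = metabolite_specs,
      n_weeks = as.integer(n_weeks),
      qc_interval = as.integer(qc_interval),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}
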