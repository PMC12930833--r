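#' Join processed intensities to subject records
#'
#' Maps study injections back to their subjects through the injection plan,
#' spreads metabolites into columns, and joins the subject table, yielding
#' the samples-by-variables tibble every downstream model consumes.
#'
#' @param subjects Subject tibble (one row per subject, keyed by `id`).
#' @param intensities Processed (typically log2) long intensity tibble.
#' @param plan Injection plan linking injections to sample ids.
#' @return Tibble with one row per subject: subject columns followed by one
#'   column per metabolite.
#' @export
assemble_dataset <- function(subjects, intensities, plan) {
  study <- plan %>%
    filter(.data$sample_type == "study") %>%
    select("injection_id", "sample_id")
  wide <- intensities %>%
    dplyr::inner_join(study, by = "injection_id") %>%
    select("sample_id", "metabolite", "intensity") %>%
    tidyr::pivot_wider(names_from = "metabolite", values_from = "intensity")
  left_join(subjects, wide, by = c(id = "sample_id"))
}

#' Predictor sets for the three diagnostic classifiers
#'
#' The three variable sets compared by the classification stage: (1) age,
#' sex, and the clinically used CSF biomarkers (amyloid-beta42, tau, ptau);
#' (2) the retained metabolite panel; (3) their union.
#'
#' @param dataset Output of [assemble_dataset()].
#' @param metabolites Character vector of metabolite column names.
#' @return Named list of predictor-name vectors:
#'   `demographics_biomarkers`, `metabolites`, `all`.
#' @export
variable_sets <- function(dataset, metabolites) {
  demo <- c("age", "sex", "abeta42", "tau", "ptau")
  missing_cols <- setdiff(c(demo, metabolites), names(dataset))
  if (length(missing_cols)) {
    abort(paste0("dataset lacks columns: ", paste(head(missing_cols, 5), collapse = ", ")))
  }
  list(
    demographics_biomarkers = demo,
    metabolites = metabolites,
    all = c(demo, metabolites)
  )
}

# Numeric predictor matrix: sex becomes a {0,1} male dummy, everything else
# must already be numeric.
build_x <- function(data, predictors) {
  cols <- lapply(predictors, function(p) {
    v <- data[[p]]
    if (p == "sex" || is.character(v) || is.factor(v)) {
      as.numeric(as.character(v) == "M")
    } else {
      as.numeric(v)
    }
  })
  x <- do.call(cbind, cols)
  colnames(x) <- predictors
  x
}
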