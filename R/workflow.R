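#' Run the full diagnostic pipeline on a synthetic cohort
#'
#' One-command orchestration: simulate a cohort, preprocess the intensity
#' table (drift correction, weekly normalization, missingness filter,
#' imputation), run the univariate screen, evaluate the three PLS-DA
#' variable sets under repeated cross-validation, and attach transductive
#' conformal p-values to a held-out test set, selecting the working
#' significance level from the label distribution. Controls are included in
#' the univariate statistics but excluded from all classification stages.
#'
#' @param config A [cohort_config()]; its seed is overridden by `seed`.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param outdir Optional directory; when given, all result tables are
#'   written as TSV together with a YAML run manifest (config hash, seed,
#'   package version) sufficient to reproduce every file.
#' @param span LOESS span for drift correction.
#' @param min_nonmissing Missingness filter threshold.
#' @param q_thr,p_thr Screen thresholds (ANOVA q-value, pairwise p).
#' @param reps,folds Repeated-CV design (default ten five-fold).
#' @param ncomp PLS components (`NULL` = inner-CV selection per fold).
#' @param test_frac Held-out fraction for the conformal stage.
#' @param eps_grid Significance grid for the conformal diagnostics.
#' @param scorer Conformal scorer, default [scorer_plsda()].
#' @return A `report_bundle` list: `qc_report`, `fits` (table of adjusted
#'   contrasts), `screen` (discriminatory metabolite names), `performance`
#'   (per variable set), `split_counts`, `tcp`, `calibration`,
#'   `label_dist`, `eps_star`, `confusion`, and `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1, outdir = NULL,
                         span = 0.75, min_nonmissing = 0.90,
                         q_thr = 0.05, p_thr = 0.05,
                         reps = 10, folds = 5, ncomp = NULL,
                         test_frac = 0.30, eps_grid = default_eps_grid(),
                         scorer = scorer_plsda()) {
  seeds <- derive_seeds(seed, 3)
  config$seed <- seeds[1]
  cohort <- generate_cohort(config)
  prep <- preprocess_intensities(cohort$intensities, cohort$plan,
    span = span, min_nonmissing = min_nonmissing
  )
  metabolites <- unique(prep$log2$metabolite)

  uni_data <- assemble_dataset(cohort$subjects, prep$log2, cohort$plan)
  fits <- fit_metabolites(uni_data, metabolites)
  screen <- screen_discriminatory(fits, q_thr = q_thr, p_thr = p_thr)

  cls_data <- assemble_dataset(cohort$subjects, prep$imputed, cohort$plan) %>%
    filter(.data$group != "Control")
  performance <- performance_table(cls_data, metabolites,
    reps = reps, folds = folds, seed = seeds[2], ncomp = ncomp
  )

  split <- stratified_split(
    mutate(cls_data, class = ifelse(.data$group == "iNPH", "iNPH", "not-iNPH")),
    response = "class", test_frac = test_frac, seed = seeds[3]
  )
  all_preds <- variable_sets(cls_data, metabolites)$all
  tcp <- tcp_predict(
    cls_data[split$train, , drop = FALSE],
    cls_data[split$test, , drop = FALSE],
    predictors = all_preds, scorer = scorer
  )
  calibration <- calibration_curve(tcp, eps_grid)
  label_dist <- label_distribution(tcp, eps_grid)
  eps_star <- select_significance(label_dist)
  confusion <- confusion_at(tcp, eps_star)

  bundle <- structure(
    list(
      qc_report = prep$report, fits = fits, screen = screen,
      performance = performance, split_counts = split$counts,
      tcp = tcp, calibration = calibration, label_dist = label_dist,
      eps_star = eps_star, confusion = confusion,
      manifest = list(
        config_hash = rlang::hash(config[setdiff(names(config), "seed")]),
        seed = seed,
        package_version = as.character(utils::packageVersion("metabocp"))
      )
    ),
    class = "report_bundle"
  )
  if (!is.null(outdir)) write_report_bundle(bundle, outdir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  print(x$qc_report)
  cat(sprintf(
    "screen: %d discriminatory metabolite(s)%s\n", length(x$screen),
    if (length(x$screen)) paste0(" (", paste(head(x$screen, 8), collapse = ", "), ")") else ""
  ))
  print(as_tibble(x$performance))
  cat(sprintf("conformal working significance level: %.2f\n", x$eps_star))
  print(x$confusion)
  invisible(x)
}

# All tables as TSV plus a YAML manifest; the manifest (config hash + seed +
# version) is what a rerun needs to reproduce every file.
write_report_bundle <- function(bundle, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  w <- function(df, name) readr::write_tsv(as_tibble(df), file.path(outdir, name))
  w(tidy(bundle$qc_report), "qc_report.tsv")
  w(bundle$fits, "metabolite_fits.tsv")
  w(tibble(metabolite = bundle$screen), "screen.tsv")
  w(bundle$performance, "performance.tsv")
  w(bundle$split_counts, "split_counts.tsv")
  w(bundle$tcp, "tcp_pvalues.tsv")
  w(bundle$calibration, "calibration.tsv")
  w(bundle$label_dist, "label_distribution.tsv")
  w(tidy(bundle$confusion), "confusion.tsv")
  yaml::write_yaml(
    c(bundle$manifest, list(eps_star = bundle$eps_star)),
    file.path(outdir, "manifest.yaml")
  )
  invisible(outdir)
}
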