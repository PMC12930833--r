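#' Age- and sex-adjusted group model for one metabolite
#'
#' Ordinary least squares of log2 intensity on diagnostic group, age, and
#' sex (additive, no interactions), on complete cases. The overall group
#' effect is an ANOVA F-test of the full model against the age+sex-only
#' model; pairwise contrasts are reference-vs-group coefficient differences
#' (reported as reference minus group, i.e. log2 fold changes of the
#' reference over each comparison group) with t-based 95 percent confidence
#' intervals and post hoc t-test p-values.
#'
#' @param data Data frame with one row per subject.
#' @param value Name of the log2 intensity column.
#' @param reference Reference group (default `"iNPH"`); contrasts are
#'   reference minus each other group.
#' @param group,age,sex Names of the group/age/sex columns.
#' @return A `metabolite_fit` object; see [tidy.metabolite_fit()] and
#'   [glance.metabolite_fit()].
#' @export
fit_metabolite_model <- function(data, value = "intensity", reference = "iNPH",
                                 group = "group", age = "age", sex = "sex") {
  d <- data.frame(
    y = data[[value]],
    group = as.character(data[[group]]),
    age = as.numeric(data[[age]]),
    sex = as.character(data[[sex]])
  )
  d <- d[complete.cases(d), , drop = FALSE]
  present <- unique(d$group)
  if (length(present) < 2) abort("need at least two groups after complete-case removal.")
  if (!reference %in% present) {
    abort(sprintf("reference group '%s' absent after complete-case removal.", reference))
  }
  d$group <- factor(d$group, levels = c(reference, sort(setdiff(present, reference))))
  # constant covariates carry no information and would alias the intercept
  covars <- c(
    if (length(unique(d$age)) > 1) "age",
    if (length(unique(d$sex)) > 1) "sex"
  )
  n_par <- length(present) + length(covars)
  if (nrow(d) <= n_par) abort("fewer complete cases than model parameters.")

  rhs_red <- if (length(covars)) paste(covars, collapse = " + ") else "1"
  full <- lm(stats::reformulate(c("group", covars), "y"), data = d)
  reduced <- lm(stats::as.formula(paste("y ~", rhs_red)), data = d)
  if (any(is.na(coef(full)))) abort("singular design: a group or covariate is aliased.")
  an <- stats::anova(reduced, full)
  sm <- summary(full)$coefficients
  df_res <- full$df.residual
  tcrit <- stats::qt(0.975, df_res)

  idx <- grep("^group", rownames(sm))
  contrasts <- tibble(
    comparison = sub("^group", "", rownames(sm)[idx]),
    # model coefficient is group-minus-reference; report reference-minus-group
    log2fc = unname(-sm[idx, "Estimate"]),
    ci_low = unname(-sm[idx, "Estimate"] - tcrit * sm[idx, "Std. Error"]),
    ci_high = unname(-sm[idx, "Estimate"] + tcrit * sm[idx, "Std. Error"]),
    p = unname(sm[idx, "Pr(>|t|)"])
  )
  structure(
    list(
      reference = reference,
      f_stat = an$F[2],
      p_anova = an$`Pr(>F)`[2],
      n_used = nrow(d),
      contrasts = contrasts,
      model = full
    ),
    class = "metabolite_fit"
  )
}

#' @export
print.metabolite_fit <- function(x, ...) {
  cat(sprintf(
    "<metabolite_fit> reference %s, F = %.3f, p = %.3g, n = %d\n",
    x$reference, x$f_stat, x$p_anova, x$n_used
  ))
  print(x$contrasts)
  invisible(x)
}

#' Tidy a metabolite fit into its pairwise contrasts
#'
#' @param x A `metabolite_fit`.
#' @param ... Unused.
#' @return Tibble with one row per reference-vs-group contrast
#'   (`comparison`, `log2fc`, `ci_low`, `ci_high`, `p`).
#' @export
tidy.metabolite_fit <- function(x, ...) x$contrasts

#' @rdname tidy.metabolite_fit
#' @return For `glance`, a one-row tibble with the ANOVA F statistic,
#'   p-value, and the number of complete cases used.
#' @export
glance.metabolite_fit <- function(x, ...) {
  tibble(f_stat = x$f_stat, p_anova = x$p_anova, n_used = x$n_used)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (q-values): `q_(i) = min_{j >= i} m p_(j) / j`,
#' capped at 1 and order-preserving.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(1e-4, 0.02, 0.03, 0.9))
bh_fdr <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Fit adjusted group models for every metabolite
#'
#' Runs [fit_metabolite_model()] per metabolite on complete cases, adjusts
#' the ANOVA p-values with [bh_fdr()] across exactly the metabolites
#' supplied (the post-filter analysis set), and returns a long, table-shaped
#' result: one row per metabolite and pairwise contrast.
#'
#' @param data Subject-level data frame: one row per subject with `group`,
#'   `age`, `sex`, and one log2-intensity column per metabolite (see
#'   [assemble_dataset()]).
#' @param metabolites Character vector of metabolite column names.
#' @param reference Reference group for all contrasts.
#' @return Tibble with columns `metabolite`, `n_used`, `f_stat`, `p_anova`,
#'   `q_anova`, `comparison`, `log2fc`, `ci_low`, `ci_high`, `p`.
#' @export
fit_metabolites <- function(data, metabolites, reference = "iNPH") {
  fits <- purrr::map(metabolites, function(m) {
    fit_metabolite_model(data, value = m, reference = reference)
  })
  q <- bh_fdr(purrr::map_dbl(fits, "p_anova"))
  purrr::map2_dfr(fits, seq_along(fits), function(f, i) {
    mutate(
      f$contrasts,
      metabolite = metabolites[i], n_used = f$n_used,
      f_stat = f$f_stat, p_anova = f$p_anova, q_anova = q[i],
      .before = 1
    )
  })
}

#' Screen for discriminatory metabolites
#'
#' A metabolite is discriminatory when its FDR-adjusted ANOVA q-value is
#' below `q_thr`, every pairwise reference-vs-group contrast has `p <
#' p_thr`, and all contrast log2 fold changes share one sign (consistent
#' separation of the reference group from every other group in the same
#' direction).
#'
#' @param fits Output of [fit_metabolites()].
#' @param q_thr ANOVA q-value threshold (default 0.05).
#' @param p_thr Pairwise contrast p-value threshold (default 0.05).
#' @return Character vector of discriminatory metabolite names (in the
#'   input's metabolite order).
#' @export
screen_discriminatory <- function(fits, q_thr = 0.05, p_thr = 0.05) {
  hits <- fits %>%
    group_by(.data$metabolite) %>%
    summarise(
      hit = dplyr::first(.data$q_anova) < q_thr &&
        all(.data$p < p_thr) &&
        (all(.data$log2fc > 0) || all(.data$log2fc < 0)),
      .groups = "drop"
    )
  sel <- hits$metabolite[hits$hit]
  sel[order(match(sel, unique(fits$metabolite)))]
}

#' Pearson correlation with a significance test
#'
#' @param data Data frame.
#' @param x,y Names of the two numeric columns; pairs with missing values
#'   are dropped.
#' @return Tibble with `r`, `p` (two-sided t-test), and `n` pairs used.
#' @export
pearson_correlate <- function(data, x, y) {
  xv <- as.numeric(data[[x]])
  yv <- as.numeric(data[[y]])
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) abort("need at least 3 complete pairs.")
  if (sd(xv) == 0 || sd(yv) == 0) abort("constant input: correlation undefined.")
  ct <- cor.test(xv, yv, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(xv))
}

#' Welch t-test of metabolite values against biopsy AD status
#'
#' Two-sided unequal-variance two-sample t-test comparing a measured value
#' between AD-positive and AD-negative cortical biopsy strata.
#'
#' @param data Data frame.
#' @param value Name of the numeric column to compare.
#' @param status Name of the binary status column (e.g. `"ADpos"` /
#'   `"ADneg"`); rows with other values or missing data are dropped.
#' @param levels The two status levels to compare.
#' @return Tibble with `t`, `p`, and the per-stratum counts.
#' @export
biopsy_ttest <- function(data, value, status = "biopsy_ad",
                         levels = c("ADpos", "ADneg")) {
  v <- as.numeric(data[[value]])
  s <- as.character(data[[status]])
  keep <- !is.na(v) & s %in% levels
  v <- v[keep]; s <- s[keep]
  n1 <- sum(s == levels[1]); n2 <- sum(s == levels[2])
  if (n1 < 2 || n2 < 2) abort("each stratum needs at least 2 observations.")
  tt <- t.test(v[s == levels[1]], v[s == levels[2]], var.equal = FALSE)
  tibble(t = unname(tt$statistic), p = tt$p.value, n_pos = n1, n_neg = n2)
}
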