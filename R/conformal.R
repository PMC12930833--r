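# Transductive conformal prediction (TCP) on top of a refittable binary
# scorer. For each test case and each candidate label the case is
# temporarily added to the training data under that label, the scorer is
# refitted on the augmented set, nonconformity scores are recomputed, and a
# p-value is the proportion of calibration scores at least as strange as
# the test case's (the case counting itself). Calibration is Mondrian
# (label-conditional) by default, giving per-class validity.

#' PLS-DA scorer for conformal prediction
#'
#' A refittable scorer: `fit(x, y01)` trains a NIPALS PLS1 model on the
#' {0,1}-coded labels and `decision(model, x)` returns predicted responses.
#' Kept deliberately lean because transduction refits it once per
#' (test case, candidate label).
#'
#' @param ncomp Number of PLS components.
#' @return A `cp_scorer` list with `fit` and `decision` functions.
#' @export
scorer_plsda <- function(ncomp = 2) {
  structure(
    list(
      fit = function(x, y01) pls1_core(x, y01, ncomp),
      decision = function(model, x) pls1_decision(model, x)
    ),
    class = "cp_scorer"
  )
}

#' Nonconformity of a decision value under a hypothesized label
#'
#' The negative signed classifier margin toward the hypothesized label:
#' `alpha = -(2 y - 1) (decision - 0.5)` with `y` in {0,1}. Larger values
#' mean the case looks stranger for that label; a decision value of exactly
#' 0.5 is equally (non)conforming for both labels (`alpha = 0`).
#'
#' @param decision Numeric decision values (predicted coded response).
#' @param label01 Hypothesized labels coded 0/1 (recycled).
#' @return Numeric nonconformity scores.
#' @export
nonconformity <- function(decision, label01) {
  -(2 * label01 - 1) * (decision - 0.5)
}

# p-value for one (test case, label): augmented refit, Mondrian or pooled
# calibration, ties counted as >=, the test point counting itself.
tcp_pvalue_one <- function(train_x, train_y01, x_new, label01, scorer,
                           mondrian = TRUE, smoothed = FALSE) {
  aug_x <- rbind(train_x, x_new)
  aug_y <- c(train_y01, label01)
  model <- scorer$fit(aug_x, aug_y)
  cal_idx <- if (mondrian) which(train_y01 == label01) else seq_along(train_y01)
  d <- scorer$decision(model, rbind(train_x[cal_idx, , drop = FALSE], x_new))
  cal_lab <- if (mondrian) rep(label01, length(cal_idx)) else train_y01[cal_idx]
  alpha <- nonconformity(d, c(cal_lab, label01))
  a_test <- alpha[length(alpha)]
  a_cal <- alpha[-length(alpha)]
  n <- length(a_cal)
  if (smoothed) {
    (sum(a_cal > a_test) + runif(1) * (sum(a_cal == a_test) + 1)) / (n + 1)
  } else {
    (sum(a_cal >= a_test) + 1) / (n + 1)
  }
}

#' Transductive conformal p-values for a test set
#'
#' For every test case, computes the TCP p-value of the positive and the
#' negative label with a refit of the scorer per (case, label) — true
#' transduction, no caching approximations. With Mondrian (label-
#' conditional) calibration, p-values under the true label are valid per
#' class; deterministic (non-smoothed) p-values are conservative and take
#' values on the grid `k / (n_label + 1)`.
#'
#' @param train,test Data frames of training and test samples.
#' @param predictors Predictor column names (see [build_x()] conventions;
#'   `sex` becomes a 0/1 dummy).
#' @param response Class column name.
#' @param positive Positive-class label.
#' @param scorer A [scorer_plsda()]-style scorer.
#' @param mondrian Label-conditional calibration (default) or pooled.
#' @param smoothed Randomized tie-breaking for exactly uniform p-values;
#'   deterministic by default for reproducibility.
#' @param seed Seed used only when `smoothed = TRUE`.
#' @return A `tcp_result` tibble: `id` (if present), `truth` (logical),
#'   `p_pos`, `p_neg`, with the positive label stored as an attribute.
#' @export
tcp_predict <- function(train, test, predictors, response = "group",
                        positive = "iNPH", scorer = scorer_plsda(),
                        mondrian = TRUE, smoothed = FALSE, seed = 1) {
  train_x <- build_x(train, predictors)
  test_x <- build_x(test, predictors)
  if (anyNA(train_x) || anyNA(test_x)) abort("predictors contain missing values; impute first.")
  y01 <- as.numeric(as_positive(train[[response]], positive))
  if (min(sum(y01 == 1), sum(y01 == 0)) < 5) {
    abort("need at least 5 training cases per label for transductive p-values.")
  }
  run <- function() {
    p_pos <- numeric(nrow(test_x))
    p_neg <- numeric(nrow(test_x))
    for (i in seq_len(nrow(test_x))) {
      xi <- test_x[i, , drop = FALSE]
      p_pos[i] <- tcp_pvalue_one(train_x, y01, xi, 1, scorer, mondrian, smoothed)
      p_neg[i] <- tcp_pvalue_one(train_x, y01, xi, 0, scorer, mondrian, smoothed)
    }
    tibble(
      id = if ("id" %in% names(test)) test$id else as.character(seq_len(nrow(test_x))),
      truth = as_positive(test[[response]], positive),
      p_pos = p_pos, p_neg = p_neg
    )
  }
  out <- if (smoothed) with_seed(seed, run()) else run()
  structure(out,
    positive = positive, mondrian = mondrian,
    class = c("tcp_result", class(tibble()))
  )
}

#' Prediction sets at a significance level
#'
#' A label is retained when its p-value exceeds the significance level
#' `eps`; the resulting set holds one label (high confidence), both labels
#' (ambiguous), or none (low confidence).
#'
#' @param tcp A `tcp_result` (or any tibble with `p_pos`, `p_neg`).
#' @param eps Significance level in `[0, 1)`.
#' @return The input with added columns `set` (`"positive"`, `"negative"`,
#'   `"both"`, `"empty"`), `cardinality` (`"single"`, `"multiple"`,
#'   `"empty"`), and `covered` (retained set contains the true label, when
#'   `truth` is present).
#' @export
predict_sets <- function(tcp, eps) {
  assert_scalar_number(eps, "eps", 0, 1 - 1e-12)
  keep_pos <- tcp$p_pos > eps
  keep_neg <- tcp$p_neg > eps
  out <- mutate(
    tcp,
    set = case_when(
      keep_pos & keep_neg ~ "both",
      keep_pos ~ "positive",
      keep_neg ~ "negative",
      TRUE ~ "empty"
    ),
    cardinality = case_when(
      .data$set == "both" ~ "multiple",
      .data$set == "empty" ~ "empty",
      TRUE ~ "single"
    )
  )
  if ("truth" %in% names(out)) {
    out$covered <- ifelse(out$truth, keep_pos, keep_neg)
  }
  out
}

default_eps_grid <- function() seq(0.01, 0.50, by = 0.01)

#' Conformal calibration curve
#'
#' Observed error rate (true label excluded from the prediction set) at
#' each significance level; under exchangeability the curve lies on or
#' below the diagonal up to Monte-Carlo noise.
#'
#' @param tcp A `tcp_result` with a `truth` column.
#' @param eps_grid Significance levels, default `0.01, 0.02, ..., 0.50`.
#' @return A `cp_calibration` tibble: `eps`, `error`, `n`.
#' @export
calibration_curve <- function(tcp, eps_grid = default_eps_grid()) {
  if (!nrow(tcp)) abort("need at least one test prediction.")
  p_true <- ifelse(tcp$truth, tcp$p_pos, tcp$p_neg)
  out <- tibble(
    eps = eps_grid,
    error = vapply(eps_grid, function(e) mean(p_true <= e), numeric(1)),
    n = nrow(tcp)
  )
  structure(out, class = c("cp_calibration", class(tibble())))
}

#' Distribution of prediction-set cardinalities across significance levels
#'
#' @inheritParams calibration_curve
#' @return A `cp_label_distribution` tibble: `eps`, `cardinality`
#'   (`single` / `multiple` / `empty`), `fraction` (summing to 1 per
#'   `eps`).
#' @export
label_distribution <- function(tcp, eps_grid = default_eps_grid()) {
  out <- purrr::map_dfr(eps_grid, function(e) {
    card <- predict_sets(tcp, e)$cardinality
    tibble(
      eps = e,
      cardinality = c("single", "multiple", "empty"),
      fraction = c(
        mean(card == "single"), mean(card == "multiple"), mean(card == "empty")
      )
    )
  })
  structure(out, class = c("cp_label_distribution", class(tibble())))
}

#' Select the working significance level
#'
#' The significance level maximizing the fraction of single-label
#' predictions; ties resolve to the smallest level (most confident
#' operating point with the same decisiveness).
#'
#' @param dist Output of [label_distribution()].
#' @return A single significance level.
#' @export
select_significance <- function(dist) {
  singles <- filter(dist, .data$cardinality == "single") %>% arrange(.data$eps)
  if (!nrow(singles)) abort("empty label distribution.")
  singles$eps[which.max(singles$fraction)]
}

#' Confusion summary at a significance level
#'
#' Tabulates true class against prediction-set outcome (single positive,
#' single negative, both, empty) and reports per-class accuracy as the
#' fraction of cases whose retained set contains the true label (single
#' correct or both).
#'
#' @inheritParams predict_sets
#' @return A `cp_confusion` list with `counts` (truth-by-outcome tibble)
#'   and `accuracy` (per-class coverage accuracy), plus `eps`.
#' @export
confusion_at <- function(tcp, eps) {
  sets <- predict_sets(tcp, eps)
  positive <- attr(tcp, "positive") %||% "positive"
  negative <- paste0("not-", positive)
  sets$true_class <- ifelse(sets$truth, positive, negative)
  counts <- sets %>%
    count(.data$true_class, .data$set) %>%
    tidyr::pivot_wider(names_from = "set", values_from = "n", values_fill = 0L)
  for (col in c("positive", "negative", "both", "empty")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- select(counts, "true_class", "positive", "negative", "both", "empty")
  accuracy <- sets %>%
    group_by(.data$true_class) %>%
    summarise(accuracy = mean(.data$covered), n = n(), .groups = "drop")
  structure(
    list(counts = counts, accuracy = accuracy, eps = eps),
    class = "cp_confusion"
  )
}

#' @export
print.cp_confusion <- function(x, ...) {
  cat(sprintf("<cp_confusion> at significance %.2f\n", x$eps))
  print(x$counts)
  print(x$accuracy)
  invisible(x)
}

#' @export
tidy.cp_confusion <- function(x, ...) {
  left_join(x$counts, x$accuracy, by = "true_class")
}
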