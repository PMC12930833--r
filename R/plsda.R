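#' Stratified train/test split
#'
#' Per class, `ceiling(test_frac * n_class)` samples go to the test set,
#' chosen uniformly at random given the seed; the rest train. With 118
#' positive and 149 negative cases at `test_frac = 0.30` this yields the
#' canonical 82/36 and 104/45 partition.
#'
#' @param data Data frame with one row per sample.
#' @param response Name of the class column.
#' @param test_frac Test fraction in `[0, 1)`.
#' @param seed Seed for the random assignment.
#' @return List with `train` and `test` row-index vectors and a `counts`
#'   tibble of per-class train/test sizes.
#' @export
stratified_split <- function(data, response = "class", test_frac = 0.30, seed = 1) {
  assert_scalar_number(test_frac, "test_frac", 0, 1 - 1e-12)
  y <- as.character(data[[response]])
  if (any(table(y) == 0) || length(unique(y)) < 1) abort("empty class in response.")
  test_idx <- with_seed(seed, {
    unlist(lapply(unique(y), function(cl) {
      rows <- which(y == cl)
      sample(rows, ceiling(test_frac * length(rows)))
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(data)), test_idx)
  counts <- tibble(class = y) %>%
    mutate(split = ifelse(row_number() %in% test_idx, "test", "train")) %>%
    count(.data$class, .data$split) %>%
    tidyr::pivot_wider(names_from = "split", values_from = "n", values_fill = 0L)
  list(train = train_idx, test = test_idx, counts = counts)
}

# --- PLS1 core (NIPALS) -----------------------------------------------------
# Autoscaled predictors, response coded {0,1} and centred. Kept as lean
# matrix code because the transductive conformal layer refits this model
# once per (test case, candidate label).

pls1_core <- function(x, y01, ncomp) {
  mx <- colMeans(x)
  sx <- apply(x, 2, sd)
  keep <- sx > 0
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, mx[keep]), 2, sx[keep], "/")
  my <- mean(y01)
  e <- xs
  f <- y01 - my
  p_dim <- ncol(xs)
  ncomp <- min(ncomp, p_dim, nrow(xs) - 1L)
  W <- matrix(0, p_dim, ncomp)
  P <- matrix(0, p_dim, ncomp)
  qv <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(e, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      ncomp <- a - 1L
      break
    }
    w <- w / nw
    t_sc <- e %*% w
    tt <- sum(t_sc^2)
    p_load <- crossprod(e, t_sc) / tt
    q_load <- sum(f * t_sc) / tt
    e <- e - t_sc %*% t(p_load)
    f <- f - t_sc * q_load
    W[, a] <- w
    P[, a] <- p_load
    qv[a] <- q_load
  }
  if (ncomp < 1L) abort("response carries no predictor signal; cannot fit PLS.")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  qv <- qv[seq_len(ncomp)]
  beta <- W %*% solve(crossprod(P, W), qv)
  list(
    beta = drop(beta), x_center = mx[keep], x_scale = sx[keep],
    y_mean = my, keep = keep, W = W, P = P, q = qv, ncomp = ncomp
  )
}

pls1_decision <- function(core, x) {
  xs <- sweep(sweep(x[, core$keep, drop = FALSE], 2, core$x_center), 2, core$x_scale, "/")
  drop(xs %*% core$beta) + core$y_mean
}

#' Fit a PLS-DA binary classifier
#'
#' Partial least squares discriminant analysis: predictors are autoscaled
#' (mean 0, SD 1, parameters stored and reapplied verbatim at prediction),
#' the class response is coded {0,1}, and a PLS regression (NIPALS) is
#' fitted. The decision value is the predicted response; a case is called
#' positive when the decision value is at least 0.5. Constant predictors
#' are dropped with a warning.
#'
#' @param x Numeric sample-by-predictor matrix (no missing values).
#' @param y Class labels: logical, or anything coercible with `positive`.
#' @param ncomp Number of PLS components. `NULL` selects it by inner 5-fold
#'   cross-validation on a 1..10 grid, minimizing error rate with ties going
#'   to fewer components.
#' @param positive Positive-class label when `y` is not logical.
#' @param inner_seed Seed for the inner component-selection folds.
#' @return A `plsda_model`.
#' @export
fit_plsda <- function(x, y, ncomp = NULL, positive = "iNPH", inner_seed = 1) {
  x <- as.matrix(x)
  if (anyNA(x)) abort("`x` must be imputed: no missing values.")
  pos <- as_positive(y, positive)
  if (length(unique(pos)) < 2) abort("response is constant; both classes required.")
  if (any(apply(x, 2, sd) == 0)) {
    warn("constant predictor(s) dropped.")
  }
  if (is.null(ncomp)) {
    ncomp <- select_ncomp(x, pos, seed = inner_seed)
  }
  if (ncomp < 1) abort("`ncomp` must be >= 1.")
  core <- pls1_core(x, as.numeric(pos), ncomp)
  structure(
    list(
      core = core, predictors = colnames(x), positive = positive,
      ncomp = core$ncomp, threshold = 0.5
    ),
    class = "plsda_model"
  )
}

# inner 5-fold CV over a component grid; ties favour fewer components
select_ncomp <- function(x, pos, grid = 1:10, folds = 5, seed = 1) {
  grid <- grid[grid <= min(ncol(x), nrow(x) - 2L)]
  fold_id <- make_folds(pos, folds, seed)
  err <- sapply(grid, function(k) {
    mean(unlist(lapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      core <- pls1_core(x[tr, , drop = FALSE], as.numeric(pos[tr]), k)
      d <- pls1_decision(core, x[!tr, , drop = FALSE])
      (d >= 0.5) != pos[!tr]
    })))
  })
  grid[which.min(err)]
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf(
    "<plsda_model> %d component(s), %d predictors, positive class '%s'\n",
    x$ncomp, length(x$predictors), x$positive
  ))
  invisible(x)
}

#' Predict from a PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param newdata Numeric matrix with the training predictors as columns.
#' @param ... Unused.
#' @return Tibble with `decision` (predicted coded response) and
#'   `predicted` (logical, positive-class call at the 0.5 threshold).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!all(object$predictors %in% colnames(newdata))) {
    abort("`newdata` lacks training predictors.")
  }
  d <- pls1_decision(object$core, newdata[, object$predictors, drop = FALSE])
  tibble(decision = d, predicted = d >= object$threshold)
}

#' Tidy PLS-DA weights and loadings
#'
#' @param x A `plsda_model`.
#' @param ... Unused.
#' @return Tibble with one row per retained predictor and component:
#'   `predictor`, `component`, `weight`, `loading`, plus the overall
#'   regression `coefficient` (repeated across components).
#' @export
tidy.plsda_model <- function(x, ...) {
  preds <- x$predictors[x$core$keep]
  purrr::map_dfr(seq_len(x$ncomp), function(a) {
    tibble(
      predictor = preds, component = a,
      weight = x$core$W[, a], loading = x$core$P[, a],
      coefficient = x$core$beta
    )
  })
}

#' @rdname tidy.plsda_model
#' @export
glance.plsda_model <- function(x, ...) {
  tibble(
    ncomp = x$ncomp, n_predictors = length(x$predictors),
    positive = x$positive, threshold = x$threshold
  )
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative, with ties counting one half.
#'
#' @param decision Numeric scores, larger meaning more positive.
#' @param truth Logical positive-class indicator.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(decision, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) abort("AUC needs both classes.")
  r <- rank(decision)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

make_folds <- function(pos, folds, seed) {
  with_seed(seed, {
    id <- integer(length(pos))
    for (cl in unique(pos)) {
      rows <- which(pos == cl)
      id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
    id
  })
}

#' Repeated stratified cross-validation of a PLS-DA classifier
#'
#' Runs `reps` independent stratified `folds`-fold cross-validations
#' (default ten five-fold, i.e. 50 held-out test sets). Autoscaling and
#' component selection happen inside each training fold only; AUC (rank
#' statistic) and error rate (misclassification at the 0.5 threshold) are
#' computed on each held-out fold and summarised as mean and SD over all
#' test sets.
#'
#' @param data Sample-by-variable data frame.
#' @param predictors Character vector of predictor columns (see
#'   [variable_sets()]).
#' @param response Class column name.
#' @param positive Positive class label.
#' @param reps,folds Repetitions and folds.
#' @param seed Master seed for fold assignment.
#' @param ncomp Components per fold model; `NULL` selects by inner CV.
#' @return A `cv_performance` tibble: `auc_mean`, `auc_sd`, `er_mean`,
#'   `er_sd`, `n_test_sets`.
#' @export
repeated_cv <- function(data, predictors, response = "group", positive = "iNPH",
                        reps = 10, folds = 5, seed = 1, ncomp = NULL) {
  x <- build_x(data, predictors)
  if (anyNA(x)) abort("predictors contain missing values; impute first.")
  pos <- as_positive(data[[response]], positive)
  if (min(table(pos)) < folds) abort("each class needs at least `folds` members.")
  seeds <- derive_seeds(seed, reps * 2)
  res <- purrr::map_dfr(seq_len(reps), function(r) {
    fold_id <- make_folds(pos, folds, seeds[r])
    purrr::map_dfr(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- fit_plsda(x[tr, , drop = FALSE], pos[tr],
        ncomp = ncomp, inner_seed = seeds[reps + r]
      )
      pr <- predict(fit, x[!tr, , drop = FALSE])
      tibble(
        rep = r, fold = f,
        auc = auc_rank(pr$decision, pos[!tr]),
        er = mean(pr$predicted != pos[!tr])
      )
    })
  })
  structure(
    tibble(
      auc_mean = mean(res$auc), auc_sd = sd(res$auc),
      er_mean = mean(res$er), er_sd = sd(res$er),
      n_test_sets = nrow(res)
    ),
    fold_results = res,
    class = c("cv_performance", class(tibble()))
  )
}

#' Compare the three diagnostic variable sets under repeated CV
#'
#' @param dataset Classification dataset (controls excluded), see
#'   [assemble_dataset()].
#' @param metabolites Metabolite column names.
#' @inheritParams repeated_cv
#' @return Tibble with one row per variable set: the [repeated_cv()]
#'   summary prefixed by `variables`.
#' @export
performance_table <- function(dataset, metabolites, response = "group",
                              positive = "iNPH", reps = 10, folds = 5,
                              seed = 1, ncomp = NULL) {
  sets <- variable_sets(dataset, metabolites)
  purrr::imap_dfr(sets, function(preds, nm) {
    perf <- repeated_cv(dataset, preds,
      response = response, positive = positive,
      reps = reps, folds = folds, seed = seed, ncomp = ncomp
    )
    mutate(as_tibble(perf), variables = nm, .before = 1)
  })
}
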