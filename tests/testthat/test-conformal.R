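test_that("nonconformity is the negative signed margin toward the label", {
  expect_equal(nonconformity(0.9, 1), -0.4)
  expect_equal(nonconformity(0.9, 0), 0.4)
  expect_equal(nonconformity(0.5, 1), 0)
  expect_equal(nonconformity(0.5, 0), 0)
})

test_that("a centroid-like point conforms to its own class and not the other", {
  set.seed(1)
  n <- 30
  train_x <- rbind(
    matrix(rnorm(n * 2, 0), n, 2),
    matrix(rnorm(n * 2, 3), n, 2)
  )
  colnames(train_x) <- c("a", "b")
  y01 <- rep(c(0, 1), each = n)
  sc <- scorer_plsda(1)
  centre_pos <- matrix(c(3, 3), 1, dimnames = list(NULL, c("a", "b")))
  p_pos <- metabocp:::tcp_pvalue_one(train_x, y01, centre_pos, 1, sc)
  p_neg <- metabocp:::tcp_pvalue_one(train_x, y01, centre_pos, 0, sc)
  expect_gt(p_pos, 0.4) # typical for its own class
  expect_lt(p_neg, 0.1) # strange under the other label
})

test_that("the p-value counting rule matches hand enumeration", {
  # calibration alphas {1,2,3,4} with the hypothesized label, alpha_test 2.5:
  # scores >= 2.5 are {3, 4} plus the point itself -> p = 3/5
  sc <- passthrough_scorer()
  d_cal <- 0.5 - c(1, 2, 3, 4) # alpha = -(d - 0.5) under label 1
  train_x <- cbind(a = d_cal, b = 0)
  x_new <- cbind(a = 0.5 - 2.5, b = 0)
  p <- metabocp:::tcp_pvalue_one(train_x, rep(1, 4), x_new, 1, sc)
  expect_equal(p, 3 / 5)

  # strictly strangest point: p = 1/(n+1); most conforming: p = 1
  x_hi <- cbind(a = 0.5 - 9, b = 0)
  expect_equal(metabocp:::tcp_pvalue_one(train_x, rep(1, 4), x_hi, 1, sc), 1 / 5)
  x_lo <- cbind(a = 0.5 - 0.5, b = 0)
  expect_equal(metabocp:::tcp_pvalue_one(train_x, rep(1, 4), x_lo, 1, sc), 1)
})

test_that("tcp p-values equal exhaustive brute-force recomputation for n <= 12", {
  set.seed(21)
  sc <- scorer_plsda(1)
  for (rep in 1:10) {
    n <- sample(10:12, 1)
    y01 <- c(rep(0, 5), rep(1, n - 5))
    train_x <- cbind(a = rnorm(n) + 1.5 * y01, b = rnorm(n))
    x_new <- cbind(a = rnorm(1), b = rnorm(1))
    for (lab in c(0, 1)) {
      expect_equal(
        metabocp:::tcp_pvalue_one(train_x, y01, x_new, lab, sc),
        tcp_oracle(train_x, y01, x_new, lab, sc)
      )
    }
  }
})

test_that("p-values live on the grid k/(n_label+1) with minimum 1/(n_label+1)", {
  set.seed(22)
  n_pos <- 9
  n_neg <- 13
  tr <- tibble::tibble(
    group = rep(c("iNPH", "other"), c(n_pos, n_neg)),
    v1 = rnorm(n_pos + n_neg) + rep(c(1, 0), c(n_pos, n_neg)),
    v2 = rnorm(n_pos + n_neg)
  )
  te <- tibble::tibble(
    group = rep(c("iNPH", "other"), 10),
    v1 = rnorm(20), v2 = rnorm(20)
  )
  tcp <- tcp_predict(tr, te, c("v1", "v2"), response = "group", scorer = scorer_plsda(1))
  grid_pos <- (1:(n_pos + 1)) / (n_pos + 1)
  grid_neg <- (1:(n_neg + 1)) / (n_neg + 1)
  expect_true(all(sapply(tcp$p_pos, function(p) any(abs(p - grid_pos) < 1e-12))))
  expect_true(all(sapply(tcp$p_neg, function(p) any(abs(p - grid_neg) < 1e-12))))
  expect_gte(min(tcp$p_pos), 1 / (n_pos + 1) - 1e-12)
  expect_gte(min(tcp$p_neg), 1 / (n_neg + 1) - 1e-12)
})

test_that("prediction sets follow the retention rule and are nested in eps", {
  tcp <- tibble::tibble(
    id = as.character(1:3), truth = c(TRUE, TRUE, FALSE),
    p_pos = c(0.50, 0.50, 0.02), p_neg = c(0.02, 0.50, 0.03)
  )
  s <- predict_sets(tcp, 0.09)
  expect_equal(s$set, c("positive", "both", "empty"))
  expect_equal(s$cardinality, c("single", "multiple", "empty"))
  expect_equal(s$covered, c(TRUE, TRUE, FALSE))

  # nestedness: larger eps can only shrink the retained set
  set.seed(23)
  rnd <- tibble::tibble(
    truth = runif(50) < 0.5,
    p_pos = sample(seq(0, 1, 0.05), 50, replace = TRUE),
    p_neg = sample(seq(0, 1, 0.05), 50, replace = TRUE)
  )
  eps_sorted <- sort(runif(6, 0, 0.9))
  retained <- lapply(eps_sorted, function(e) {
    s <- predict_sets(rnd, e)
    cbind(s$p_pos > e, s$p_neg > e)
  })
  for (k in seq_len(length(retained) - 1)) {
    expect_true(all(retained[[k + 1]] <= retained[[k]]))
  }
})

test_that("calibration curve boundary behaviour and monotone error", {
  set.seed(24)
  tcp <- tibble::tibble(
    truth = runif(40) < 0.5,
    p_pos = sample(seq(0.05, 1, 0.05), 40, replace = TRUE),
    p_neg = sample(seq(0.05, 1, 0.05), 40, replace = TRUE)
  )
  cal <- calibration_curve(tcp, c(0, 0.2, 0.5, 0.99))
  expect_equal(cal$error[1], 0) # p-values are strictly positive
  expect_equal(cal$error[4], 1, tolerance = 0.26) # near 1 as eps -> 1
  expect_true(all(diff(cal$error) >= 0))
})

test_that("label distribution fractions sum to one with the right limits", {
  set.seed(25)
  tcp <- tibble::tibble(
    truth = runif(30) < 0.5,
    p_pos = runif(30, 0.01, 0.99), p_neg = runif(30, 0.01, 0.99)
  )
  dist <- label_distribution(tcp, c(0.005, 0.2, 0.995))
  sums <- tapply(dist$fraction, dist$eps, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(dist$fraction[dist$eps == 0.005 & dist$cardinality == "multiple"], 1)
  expect_equal(dist$fraction[dist$eps == 0.995 & dist$cardinality == "empty"], 1)
})

test_that("significance selection maximizes single-label fraction, ties to smallest", {
  mk_dist <- function(eps, single) {
    structure(
      dplyr::bind_rows(
        tibble::tibble(eps = eps, cardinality = "single", fraction = single),
        tibble::tibble(eps = eps, cardinality = "multiple", fraction = 1 - single)
      ),
      class = c("cp_label_distribution", class(tibble::tibble()))
    )
  }
  d1 <- mk_dist(c(0.05, 0.09, 0.20), c(0.5, 0.9, 0.7))
  expect_equal(select_significance(d1), 0.09)
  d2 <- mk_dist(c(0.05, 0.10), c(0.8, 0.8))
  expect_equal(select_significance(d2), 0.05)
  d3 <- mk_dist(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(select_significance(d3), 0.3)
})

test_that("confusion summary reproduces per-class coverage accuracy arithmetic", {
  # 35 true-positive cases: 27 correct single, 6 both, 2 wrong single
  eps <- 0.09
  tcp <- structure(
    tibble::tibble(
      id = as.character(1:40),
      truth = rep(c(TRUE, FALSE), c(35, 5)),
      p_pos = c(rep(0.5, 27), rep(0.5, 6), rep(0.01, 2), rep(0.01, 5)),
      p_neg = c(rep(0.01, 27), rep(0.5, 6), rep(0.5, 2), rep(0.5, 5))
    ),
    positive = "iNPH",
    class = c("tcp_result", class(tibble::tibble()))
  )
  conf <- confusion_at(tcp, eps)
  acc <- conf$accuracy
  expect_equal(acc$accuracy[acc$true_class == "iNPH"], (27 + 6) / 35)
  expect_equal(round(100 * acc$accuracy[acc$true_class == "iNPH"]), 94)
  counts <- conf$counts
  inph_row <- counts[counts$true_class == "iNPH", ]
  expect_equal(inph_row$positive, 27L)
  expect_equal(inph_row$both, 6L)
  expect_equal(inph_row$negative, 2L)
  expect_equal(sum(inph_row[, c("positive", "negative", "both", "empty")]), 35)

  # all single and correct -> 100%; all empty -> 0% and everything in empty
  perfect <- structure(
    tibble::tibble(truth = c(TRUE, FALSE), p_pos = c(0.9, 0.01), p_neg = c(0.01, 0.9)),
    positive = "iNPH", class = c("tcp_result", class(tibble::tibble()))
  )
  expect_true(all(confusion_at(perfect, 0.09)$accuracy$accuracy == 1))
  empty <- structure(
    tibble::tibble(truth = c(TRUE, FALSE), p_pos = c(0.01, 0.01), p_neg = c(0.01, 0.01)),
    positive = "iNPH", class = c("tcp_result", class(tibble::tibble()))
  )
  conf_e <- confusion_at(empty, 0.09)
  expect_true(all(conf_e$accuracy$accuracy == 0))
  expect_equal(sum(conf_e$counts$empty), 2)
})

test_that("true-label p-values are stochastically conservative (validity)", {
  set.seed(26)
  mk <- function(n) {
    y <- runif(n) < 0.5
    tibble::tibble(
      class = ifelse(y, "iNPH", "other"),
      v1 = rnorm(n) + y, v2 = rnorm(n) + 0.5 * y
    )
  }
  p_true <- unlist(lapply(1:20, function(s) {
    set.seed(100 + s)
    tr <- mk(60)
    te <- mk(40)
    tcp <- tcp_predict(tr, te, c("v1", "v2"),
      response = "class", scorer = scorer_plsda(1)
    )
    ifelse(tcp$truth, tcp$p_pos, tcp$p_neg)
  }))
  # one-sided KS: cannot reject that P(p <= t) <= t (conservative p-values);
  # ties are inherent (p-values are discrete), so the ties warning is muted
  ks <- suppressWarnings(stats::ks.test(p_true, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("smoothed p-values are reproducible under a seed and differ across seeds", {
  set.seed(27)
  tr <- tibble::tibble(
    class = rep(c("iNPH", "other"), each = 10),
    v1 = rnorm(20) + rep(c(1, 0), each = 10), v2 = rnorm(20)
  )
  te <- tibble::tibble(class = c("iNPH", "other"), v1 = rnorm(2), v2 = rnorm(2))
  a <- tcp_predict(tr, te, c("v1", "v2"),
    response = "class", scorer = scorer_plsda(1), smoothed = TRUE, seed = 1
  )
  b <- tcp_predict(tr, te, c("v1", "v2"),
    response = "class", scorer = scorer_plsda(1), smoothed = TRUE, seed = 1
  )
  c <- tcp_predict(tr, te, c("v1", "v2"),
    response = "class", scorer = scorer_plsda(1), smoothed = TRUE, seed = 2
  )
  expect_equal(a$p_pos, b$p_pos)
  expect_false(identical(a$p_pos, c$p_pos))
})
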