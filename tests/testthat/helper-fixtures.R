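# Shared fixtures and independent oracles, all built in code at test time.

# small two-group cohort configuration for fast end-to-end runs
small_config <- function(seed = 1, n_metab = 6, drift = 0.3, censor = 0.05,
                         group_sizes = c(iNPH = 24, AD = 20), ...) {
  specs <- lapply(seq_len(n_metab), function(i) {
    metabolite_spec(
      name = sprintf("m%02d", i),
      base_log2 = 12 + i,
      group_offsets = if (i == 1) c(AD = 0.5) else c(),
      subject_sd = 0.5,
      drift_amplitude = drift,
      censor_quantile = censor
    )
  })
  cohort_config(
    group_sizes = group_sizes, metabolite_specs = specs,
    n_weeks = 2, qc_interval = 5, seed = seed, ...
  )
}

# hand-rolled intensity table + plan for exact-arithmetic preprocessing checks
tiny_plan <- function(values_by_week) {
  purrr::imap_dfr(values_by_week, function(types, w) {
    tibble::tibble(
      injection_id = sprintf("w%d_i%02d", as.integer(w), seq_along(types)),
      sample_id = ifelse(types == "study",
        sprintf("s_w%s_%02d", w, seq_along(types)), NA_character_
      ),
      week = as.integer(w),
      run_order = seq_along(types),
      sample_type = types
    )
  })
}

tiny_intensities <- function(plan, values, metabolite = "m1") {
  tibble::tibble(
    metabolite = metabolite,
    injection_id = plan$injection_id,
    intensity = values
  )
}

# independent brute-force step-up FDR: q_i = min_{j >= rank(p_i)} m p_(j) / j,
# enumerated literally from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ps <- sort(p)
  sapply(p, function(pi) {
    ri <- which(ps >= pi - 1e-15)[1]
    min(1, min(sapply(ri:m, function(j) m * ps[j] / j)))
  })
}

# brute-force transductive p-value: explicit augmented refit and counting
tcp_oracle <- function(train_x, train_y01, x_new, label01, scorer) {
  aug_x <- rbind(train_x, x_new)
  aug_y <- c(train_y01, label01)
  model <- scorer$fit(aug_x, aug_y)
  same <- which(aug_y == label01)
  alphas <- sapply(same, function(i) {
    d <- scorer$decision(model, aug_x[i, , drop = FALSE])
    -(2 * label01 - 1) * (d - 0.5)
  })
  a_test <- alphas[length(alphas)]
  sum(alphas >= a_test) / length(same)
}

# scorer whose decision is just the first feature: alphas fully controllable
passthrough_scorer <- function() {
  structure(
    list(
      fit = function(x, y01) NULL,
      decision = function(model, x) x[, 1]
    ),
    class = "cp_scorer"
  )
}
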