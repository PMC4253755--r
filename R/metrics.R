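#' Error metrics between estimated and reference values
#'
#' Mean absolute error, mean squared error, mean relative error
#' (mean of |e - r| / |r|) and root mean squared error.
#'
#' @param estimated,reference Equal-length numeric vectors.
#' @return A one-row tibble: `mae`, `mse`, `mre`, `rmse`.
#' @examples
#' error_metrics(c(60, 55), c(58, 57))
#' @export
error_metrics <- function(estimated, reference) {
  check_paired(estimated, reference, min_n = 1)
  if (any(reference == 0)) abort("reference contains zeros: MRE undefined")
  d <- estimated - reference
  mse <- mean(d^2)
  tibble(
    mae = mean(abs(d)),
    mse = mse,
    mre = mean(abs(d) / abs(reference)),
    rmse = sqrt(mse)
  )
}

check_paired <- function(estimated, reference, min_n = 2) {
  if (length(estimated) != length(reference)) {
    abort("estimated and reference must have equal length")
  }
  if (length(estimated) < min_n) {
    abort(sprintf("need at least %d paired values", min_n))
  }
  if (!all(is.finite(estimated)) || !all(is.finite(reference))) {
    abort("values must be finite")
  }
  invisible(TRUE)
}

#' Ordinary least squares of estimated on reference
#'
#' @inheritParams error_metrics
#' @return A one-row tibble: `slope`, `intercept`, `pearson_r`.
#' @export
linear_regression <- function(estimated, reference) {
  check_paired(estimated, reference)
  if (sd(reference) == 0) abort("reference is constant: regression undefined")
  fit <- lm(estimated ~ reference)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    pearson_r = if (sd(estimated) == 0) NA_real_ else cor(estimated, reference)
  )
}

#' Bland-Altman agreement statistics
#'
#' Differences d = estimated - reference; bias = mean(d); limits of agreement
#' = bias +/- 1.96 x sample SD (denominator n - 1).
#'
#' @inheritParams error_metrics
#' @return A one-row tibble: `bias`, `loa_low`, `loa_high`, `sd_diff`.
#' @export
bland_altman <- function(estimated, reference) {
  check_paired(estimated, reference)
  d <- estimated - reference
  s <- sd(d)
  tibble(
    bias = mean(d),
    loa_low = mean(d) - 1.96 * s,
    loa_high = mean(d) + 1.96 * s,
    sd_diff = s
  )
}

#' Two-sided paired t-test p-value
#'
#' By convention, identically zero differences give p = 1 (no evidence of a
#' systematic difference); a nonzero constant difference gives p = 0 (the
#' degenerate limit of the t statistic).
#'
#' @inheritParams error_metrics
#' @return A single p-value.
#' @export
paired_test <- function(estimated, reference) {
  check_paired(estimated, reference)
  d <- estimated - reference
  if (sd(d) == 0) {
    return(if (mean(d) == 0) 1 else 0)
  }
  unname(t.test(estimated, reference, paired = TRUE)$p.value)
}

#' Full agreement report between estimated and reference values
#'
#' Bundles [error_metrics()], [linear_regression()], [bland_altman()] and
#' [paired_test()] into one object with [tidy()], [glance()] and
#' [autoplot()] methods — the package's counterpart of a method-vs-expert
#' validation table with regression and Bland-Altman panels.
#'
#' @inheritParams error_metrics
#' @param label Name of the quantity being compared (used in plots).
#' @return A list of class `lv_agreement`.
#' @export
agreement_report <- function(estimated, reference, label = "EF (%)") {
  check_paired(estimated, reference)
  structure(
    list(
      data = tibble(estimated = estimated, reference = reference),
      label = label,
      errors = error_metrics(estimated, reference),
      regression = linear_regression(estimated, reference),
      bland_altman = bland_altman(estimated, reference),
      p_value = paired_test(estimated, reference),
      n = length(estimated)
    ),
    class = "lv_agreement"
  )
}

#' @export
print.lv_agreement <- function(x, ...) {
  cat(sprintf("<lv_agreement> %s, n = %d\n", x$label, x$n))
  cat(sprintf(
    "  MAE %.4f  MSE %.4f  MRE %.4f  RMSE %.4f\n",
    x$errors$mae, x$errors$mse, x$errors$mre, x$errors$rmse
  ))
  cat(sprintf(
    "  regression: slope %.3f  intercept %.3f  r %.3f\n",
    x$regression$slope, x$regression$intercept, x$regression$pearson_r
  ))
  cat(sprintf(
    "  Bland-Altman: bias %.3f  LoA [%.3f, %.3f]\n",
    x$bland_altman$bias, x$bland_altman$loa_low, x$bland_altman$loa_high
  ))
  cat(sprintf("  paired t-test: p = %.4f\n", x$p_value))
  invisible(x)
}

#' Tidy an agreement report
#'
#' @param x An `lv_agreement`.
#' @param ... Unused.
#' @return A tibble with `metric`, `value` rows for every reported statistic.
#' @export
tidy.lv_agreement <- function(x, ...) {
  g <- glance(x)
  tibble(metric = names(g), value = as.numeric(g[1, ]))
}

#' One-row summary of an agreement report
#'
#' @inheritParams tidy.lv_agreement
#' @return A one-row tibble mirroring the agreement fields: `mae`, `mse`,
#'   `mre`, `rmse`, `regression_slope`, `regression_intercept`, `pearson_r`,
#'   `ba_bias`, `ba_loa_low`, `ba_loa_high`, `p_value`, `n`.
#' @export
glance.lv_agreement <- function(x, ...) {
  tibble(
    mae = x$errors$mae, mse = x$errors$mse, mre = x$errors$mre,
    rmse = x$errors$rmse,
    regression_slope = x$regression$slope,
    regression_intercept = x$regression$intercept,
    pearson_r = x$regression$pearson_r,
    ba_bias = x$bland_altman$bias,
    ba_loa_low = x$bland_altman$loa_low,
    ba_loa_high = x$bland_altman$loa_high,
    p_value = x$p_value,
    n = x$n
  )
}

#' Simulate a multi-case EF validation study
#'
#' Draws reference ejection fractions uniformly and adds Gaussian
#' measurement error to produce "estimated" values, emulating the shape of a
#' method-vs-expert comparison across a cohort.
#'
#' @param n_cases Number of cases.
#' @param ef_range Reference EF range (percent), drawn uniformly.
#' @param noise_sd SD of the additive measurement error (EF points).
#' @param seed Integer seed.
#' @return A tibble: `case_id`, `reference`, `estimated`.
#' @export
simulate_ef_study <- function(n_cases = 44, ef_range = c(30, 70),
                              noise_sd = 2, seed = 1L) {
  with_local_seed(as.integer(seed), function() {
    ref <- runif(n_cases, ef_range[1], ef_range[2])
    tibble(
      case_id = seq_len(n_cases),
      reference = ref,
      estimated = ref + rnorm(n_cases, 0, noise_sd)
    )
  })
}
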