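#' Tidy an estimate table into broom conventions
#'
#' @param x An `mr_estimate` tibble (one row per estimator).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high` (confidence bounds on the OR
#'   scale).
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble(
    term = x$method,
    estimate = x$beta,
    std.error = x$se,
    statistic = x$beta / x$se,
    p.value = x$pvalue,
    conf.low = x$ci_low,
    conf.high = x$ci_high
  )
}

#' One-row summary of an MR-PRESSO run
#'
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @return One-row tibble with the global statistic, outlier count, and
#'   distortion test.
#' @export
glance.mr_presso <- function(x, ...) {
  tibble(
    rss_obs = x$rss_obs,
    global_pvalue = x$global_pvalue,
    n_snps = x$n_snps,
    n_outliers = length(x$outlier_indices),
    corrected_beta = if (is.null(x$corrected)) NA_real_ else x$corrected$beta,
    distortion_pct = x$distortion_pct,
    distortion_pvalue = x$distortion_pvalue
  )
}

#' Per-instrument view of an MR-PRESSO run
#'
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @return A tibble with one row per instrument: adjusted outlier p-value
#'   and flag.
#' @export
tidy.mr_presso <- function(x, ...) {
  tibble(
    index = seq_len(x$n_snps),
    outlier_pvalue = x$outlier_pvalues,
    outlier = seq_len(x$n_snps) %in% x$outlier_indices
  )
}

#' All per-cohort estimates from a pipeline run
#'
#' @param x An `mr_pipeline` object.
#' @param ... Unused.
#' @return The stacked estimate tibble (every method, every cohort).
#' @export
tidy.mr_pipeline <- function(x, ...) {
  as_tibble(x$estimates)
}

#' One-row combined result of a pipeline run
#'
#' @param x An `mr_pipeline` object.
#' @param ... Unused.
#' @return The meta-analysis row with exposure/outcome labels attached.
#' @export
glance.mr_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    tibble(exposure = x$exposure_name, outcome = x$outcome_name),
    as_tibble(x$meta)
  )
}
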