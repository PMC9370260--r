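#' Reconstruct a log-OR and SE from a printed OR and 95% CI
#'
#' `beta = ln(OR)` and `se = (ln(ci_high) - ln(ci_low)) / (2 * 1.959964)`.
#' A published CI that is not symmetric on the log scale (relative error of
#' the reconstructed bounds above 1%) triggers a warning, since the
#' reconstruction then only approximates the original estimate.
#'
#' @param or_ Odds ratio (> 0).
#' @param ci_low,ci_high 95% confidence bounds on the OR scale, with
#'   `0 < ci_low < or_ < ci_high`.
#' @param cohort,exposure,outcome Optional labels carried into the result.
#' @return One-row tibble in the cohort-estimate layout (`cohort`,
#'   `exposure`, `outcome`, `beta`, `se`, `or`, `ci_low`, `ci_high`,
#'   `pvalue`, `source = "reconstructed_from_ci"`).
#' @export
#' @examples
#' estimate_from_ci(0.774, 0.608, 0.985) # UK Biobank-style printed row
estimate_from_ci <- function(or_, ci_low, ci_high, cohort = NA_character_,
                             exposure = NA_character_,
                             outcome = NA_character_) {
  if (!(0 < ci_low && ci_low < or_ && or_ < ci_high)) {
    abort("Require 0 < ci_low < or_ < ci_high.")
  }
  beta <- log(or_)
  se <- (log(ci_high) - log(ci_low)) / (2 * Z95)
  rel_err <- max(abs(exp(beta - Z95 * se) - ci_low) / ci_low,
                 abs(exp(beta + Z95 * se) - ci_high) / ci_high)
  if (rel_err > 0.01) {
    warn(sprintf(
      "CI is asymmetric on the log scale (relative error %.2f%%); reconstruction is approximate.",
      100 * rel_err
    ))
  }
  tibble(
    cohort = cohort, exposure = exposure, outcome = outcome,
    beta = beta, se = se, or = or_, ci_low = ci_low, ci_high = ci_high,
    pvalue = p_normal(beta, se), source = "reconstructed_from_ci"
  )
}

#' Assign the Bonferroni significance tier
#'
#' `"significant"` below 0.01 (0.05 corrected for five outcomes),
#' `"suggestive"` in \[0.01, 0.05), `"null"` otherwise.
#'
#' @param pvalue P-value(s) in (0, 1\].
#' @return Character vector of tiers.
#' @export
classify_tier <- function(pvalue) {
  dplyr::case_when(
    pvalue < 0.01 ~ "significant",
    pvalue < 0.05 ~ "suggestive",
    TRUE ~ "null"
  )
}

#' Inverse-variance meta-analysis of cohort estimates
#'
#' Combines per-cohort causal log-ORs with weights `1/se^2`. The
#' fixed-effect SE is `(sum w)^(-1/2)`; under `model = "auto"` a
#' DerSimonian-Laird random-effects model (additive tau^2) replaces it when
#' the cross-cohort heterogeneity p-value is below 0.05. P-values are
#' two-sided normal; the Bonferroni tier is attached.
#'
#' @param cohorts Data frame of cohort estimates with columns `beta` and
#'   `se` (e.g. rows from [estimate_from_ci()] or computed estimates).
#' @param model `"auto"` (default), `"fixed"`, or `"random"`.
#' @return One-row tibble of class `"mr_meta"`: `beta`, `se`, `or`,
#'   `ci_low`, `ci_high`, `pvalue`, `q`, `q_df`, `q_pvalue`, `i2`, `tau2`,
#'   `model`, `tier`, `n_cohorts`.
#' @export
#' @examples
#' ukb <- estimate_from_ci(0.774, 0.608, 0.985)
#' fin <- estimate_from_ci(0.738, 0.504, 1.081)
#' meta_combine(rbind(ukb, fin))
meta_combine <- function(cohorts, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  cohorts <- as_tibble(cohorts)
  k <- nrow(cohorts)
  if (k < 1) abort("No cohort estimates supplied.")
  if (k == 1) {
    warn("Single cohort: returning it unchanged (no combination possible).")
    out <- tibble(
      beta = cohorts$beta, se = cohorts$se, or = exp(cohorts$beta),
      ci_low = exp(cohorts$beta - Z95 * cohorts$se),
      ci_high = exp(cohorts$beta + Z95 * cohorts$se),
      pvalue = p_normal(cohorts$beta, cohorts$se),
      q = NA_real_, q_df = 0L, q_pvalue = NA_real_, i2 = NA_real_,
      tau2 = NA_real_, model = "not_applicable",
      tier = classify_tier(p_normal(cohorts$beta, cohorts$se)),
      n_cohorts = 1L
    )
    class(out) <- c("mr_meta", class(out))
    return(out)
  }
  w <- 1 / cohorts$se^2
  beta_fixed <- sum(w * cohorts$beta) / sum(w)
  q <- sum(w * (cohorts$beta - beta_fixed)^2)
  df <- k - 1L
  q_pvalue <- pchisq(q, df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  if (model == "auto") model <- if (q_pvalue < 0.05) "random" else "fixed"
  tau2 <- 0
  if (model == "random") {
    c_dl <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - df) / c_dl)
  }
  w_star <- 1 / (cohorts$se^2 + tau2)
  beta <- sum(w_star * cohorts$beta) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  pvalue <- p_normal(beta, se)
  out <- tibble(
    beta = beta, se = se, or = exp(beta),
    ci_low = exp(beta - Z95 * se), ci_high = exp(beta + Z95 * se),
    pvalue = pvalue,
    q = q, q_df = df, q_pvalue = q_pvalue, i2 = i2, tau2 = tau2,
    model = model, tier = classify_tier(pvalue), n_cohorts = k
  )
  class(out) <- c("mr_meta", class(out))
  out
}
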