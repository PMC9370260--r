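#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Detects horizontal pleiotropy as excess residual heterogeneity around the
#' leave-one-out IVW fits and identifies the responsible instruments.
#'
#' The observed statistic is the weighted residual sum of squares
#' `RSS = sum_j (beta_out_j - theta_(-j) * beta_exp_j)^2 / se_out_j^2`,
#' where `theta_(-j)` is the fixed-effect IVW estimate computed without
#' instrument `j`. Its null distribution is simulated parametrically:
#' exposure effects are redrawn from `N(beta_exp_j, se_exp_j^2)` and outcome
#' effects from `N(theta_(-j) * beta_exp_j, se_out_j^2)`, and the RSS is
#' recomputed on each draw. The global p-value is the `+1`-corrected
#' empirical tail probability. When it falls below 0.05, each instrument's
#' observed squared residual is compared with its own simulated residuals to
#' give a per-SNP empirical p-value, Bonferroni-adjusted across instruments;
#' instruments below `outlier_alpha` are flagged, the IVW estimate is
#' recomputed without them, and a distortion test compares the shift in the
#' estimate against the shifts produced by removing equally many randomly
#' chosen instruments (informational; it does not gate anything).
#'
#' @param harmonized Harmonized-instruments data frame (>= 4 usable rows).
#' @param n_sim Number of parametric simulations for the null (default
#'   1000).
#' @param outlier_alpha Significance level applied to the
#'   Bonferroni-adjusted per-SNP p-values (default 0.05).
#' @param seed RNG seed; results are bit-for-bit reproducible given
#'   `(n_sim, seed)`.
#' @return An object of class `"mr_presso"`: a list with `rss_obs`,
#'   `global_pvalue`, `outlier_indices`, `outlier_snps`, `outlier_pvalues`
#'   (adjusted, length J, `NA` when the global test is not significant),
#'   `corrected` (IVW estimate tibble after outlier removal, `NULL` when no
#'   outliers), `distortion_pct`, `distortion_pvalue`, and the settings
#'   used.
#' @export
mr_presso <- function(harmonized, n_sim = 1000, outlier_alpha = 0.05,
                      seed = 1) {
  h <- kept_instruments(harmonized)
  check_n_instruments(h, 4, "mr_presso")
  J <- nrow(h)
  sy2 <- h$se_out^2

  loo_theta <- function(bx, by) {
    w <- (bx / h$se_out)^2
    th <- by / bx
    (sum(w * th) - w * th) / (sum(w) - w)
  }
  rss_of <- function(bx, by) {
    r <- by - loo_theta(bx, by) * bx
    sum(r^2 / sy2)
  }

  theta_loo <- loo_theta(h$beta_exp, h$beta_out)
  resid_obs <- h$beta_out - theta_loo * h$beta_exp
  rss_obs <- sum(resid_obs^2 / sy2)

  sims <- with_seed(seed, {
    bx_star <- matrix(rnorm(n_sim * J, mean = rep(h$beta_exp, each = n_sim),
                            sd = rep(h$se_exp, each = n_sim)), nrow = n_sim)
    by_star <- matrix(rnorm(n_sim * J,
                            mean = rep(theta_loo * h$beta_exp, each = n_sim),
                            sd = rep(h$se_out, each = n_sim)), nrow = n_sim)
    w_star <- sweep(bx_star^2, 2, sy2, "/")
    th_star <- by_star / bx_star
    a <- rowSums(w_star * th_star)
    b <- rowSums(w_star)
    th_loo_star <- (a - w_star * th_star) / (b - w_star)
    r_star <- by_star - th_loo_star * bx_star
    r2_star <- sweep(r_star^2, 2, sy2, "/")
    list(rss = rowSums(r2_star), resid2 = r2_star)
  })
  global_pvalue <- (1 + sum(sims$rss >= rss_obs)) / (1 + n_sim)

  outlier_pvalues <- rep(NA_real_, J)
  outlier_idx <- integer(0)
  corrected <- NULL
  distortion_pct <- NA_real_
  distortion_pvalue <- NA_real_

  if (global_pvalue < 0.05) {
    obs2 <- resid_obs^2 / sy2
    p_raw <- (1 + colSums(sims$resid2 >= rep(obs2, each = n_sim))) / (1 + n_sim)
    outlier_pvalues <- p.adjust(p_raw, method = "bonferroni")
    outlier_idx <- which(outlier_pvalues < outlier_alpha)
    if (length(outlier_idx) == J) {
      abort("Every instrument was flagged as an outlier; no corrected estimate is possible.",
            class = "mrpipe_degenerate_correction")
    }
    if (length(outlier_idx) > 0) {
      retained <- h[-outlier_idx, ]
      corrected <- mr_ivw(retained, model = "auto")
      beta_all <- mr_ivw(h, model = "fixed")$beta
      distortion_obs <- (corrected$beta - beta_all) / abs(beta_all)
      distortion_pct <- 100 * distortion_obs
      n_remove <- length(outlier_idx)
      w_all <- (h$beta_exp / h$se_out)^2
      th_all <- h$beta_out / h$beta_exp
      sw <- sum(w_all)
      swt <- sum(w_all * th_all)
      d_null <- with_seed(seed + 1L, {
        vapply(seq_len(n_sim), function(i) {
          drop_i <- sample.int(J, n_remove)
          b <- (swt - sum(w_all[drop_i] * th_all[drop_i])) /
            (sw - sum(w_all[drop_i]))
          (b - beta_all) / abs(beta_all)
        }, numeric(1))
      })
      distortion_pvalue <- (1 + sum(abs(d_null) >= abs(distortion_obs))) /
        (1 + n_sim)
    }
  }

  structure(
    list(
      rss_obs = rss_obs,
      global_pvalue = global_pvalue,
      outlier_indices = outlier_idx,
      outlier_snps = h$snp[outlier_idx],
      outlier_pvalues = outlier_pvalues,
      corrected = corrected,
      distortion_pct = distortion_pct,
      distortion_pvalue = distortion_pvalue,
      n_snps = J,
      settings = list(n_sim = n_sim, outlier_alpha = outlier_alpha,
                      seed = seed)
    ),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("MR-PRESSO (", x$n_snps, " instruments, ", x$settings$n_sim,
      " simulations)\n", sep = "")
  cat(sprintf("  Global RSS = %.4g, p = %.4g\n", x$rss_obs, x$global_pvalue))
  if (length(x$outlier_indices) > 0) {
    cat("  Outliers:", paste(x$outlier_snps, collapse = ", "), "\n")
    cat(sprintf("  Corrected IVW log-OR = %.4f (SE %.4f); distortion %.1f%% (p = %.3g)\n",
                x$corrected$beta, x$corrected$se, x$distortion_pct,
                x$distortion_pvalue))
  } else {
    cat("  No outliers flagged.\n")
  }
  invisible(x)
}
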