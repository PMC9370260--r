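# Per-SNP ratio estimates and inverse-variance weights shared by the
# estimators: theta_j = beta_out/beta_exp with first-order SE se_out/|beta_exp|,
# so w_j = (beta_exp/se_out)^2 is the inverse ratio variance (exposure
# uncertainty ignored, the usual NO-Measurement-Error approximation).
ratio_terms <- function(h) {
  if (any(h$beta_exp == 0)) {
    abort("Instrument with beta_exp = 0: Wald ratio undefined.")
  }
  list(
    theta = h$beta_out / h$beta_exp,
    se = h$se_out / abs(h$beta_exp),
    w = (h$beta_exp / h$se_out)^2
  )
}

#' Wald ratio estimate from a single instrument
#'
#' @param harmonized Harmonized-instruments data frame with exactly one
#'   usable row (extra rows are an error).
#' @return One-row estimate tibble (`method = "wald"`).
#' @export
wald_ratio <- function(harmonized) {
  h <- kept_instruments(harmonized)
  if (nrow(h) != 1L) abort("wald_ratio expects exactly one instrument.")
  rt <- ratio_terms(h)
  new_mr_estimate("wald", rt$theta, rt$se, p_normal(rt$theta, rt$se),
                  1L, "not_applicable")
}

#' Cochran's Q heterogeneity test across instrument ratios
#'
#' `Q = sum w_j (theta_j - beta)^2` with inverse-variance weights, referred
#' to a chi-square with `J - 1` degrees of freedom;
#' `I^2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param harmonized Harmonized-instruments data frame (>= 2 usable rows).
#' @param beta Pooled causal estimate the ratios are compared against
#'   (usually the fixed-effect IVW estimate).
#' @return One-row tibble `q`, `q_df`, `q_pvalue`, `i2`.
#' @export
cochran_q <- function(harmonized, beta) {
  h <- kept_instruments(harmonized)
  check_n_instruments(h, 2, "cochran_q")
  rt <- ratio_terms(h)
  q <- sum(rt$w * (rt$theta - beta)^2)
  df <- nrow(h) - 1L
  tibble(
    q = q,
    q_df = df,
    q_pvalue = pchisq(q, df, lower.tail = FALSE),
    i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0
  )
}

#' Inverse-variance weighted estimator
#'
#' Weighted mean of per-SNP Wald ratios with weights `(beta_exp/se_out)^2`.
#' The fixed-effect SE is `(sum w)^(-1/2)`; the random-effects (multiplicative
#' overdispersion) model inflates it by `max(1, sqrt(Q/(J-1)))`. `model =
#' "auto"` selects random effects when the heterogeneity p-value is below
#' 0.05, the conventional gate.
#'
#' @param harmonized Harmonized-instruments data frame (>= 2 usable rows).
#' @param model `"auto"` (default), `"fixed"`, or `"random"`.
#' @return One-row estimate tibble with heterogeneity columns `q`, `q_df`,
#'   `q_pvalue`, `i2` appended.
#' @export
mr_ivw <- function(harmonized, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  h <- kept_instruments(harmonized)
  check_n_instruments(h, 2, "mr_ivw")
  rt <- ratio_terms(h)
  beta <- sum(rt$w * rt$theta) / sum(rt$w)
  se_fixed <- 1 / sqrt(sum(rt$w))
  qres <- cochran_q(h, beta)
  if (model == "auto") {
    model <- if (qres$q_pvalue < 0.05) "random" else "fixed"
  }
  se <- if (model == "random") {
    se_fixed * max(1, sqrt(qres$q / qres$q_df))
  } else {
    se_fixed
  }
  out <- new_mr_estimate("ivw", beta, se, p_normal(beta, se), nrow(h), model)
  dplyr::bind_cols(out, qres)
}

# Profile log-likelihood for the causal slope theta under the bivariate
# normal measurement model beta_exp_j ~ N(gamma_j, se_exp_j^2),
# beta_out_j ~ N(theta * gamma_j, se_out_j^2). Given theta the nuisance
# means gamma_j maximize in closed form, leaving a 1-D profile.
ml_profile_loglik <- function(theta, bx, by, sx2, sy2) {
  gamma <- (bx / sx2 + theta * by / sy2) / (1 / sx2 + theta^2 / sy2)
  -0.5 * sum((bx - gamma)^2 / sx2 + (by - theta * gamma)^2 / sy2)
}

#' Maximum-likelihood estimator
#'
#' Maximizes the joint normal likelihood in which each instrument's true
#' exposure effect is a nuisance mean and the outcome effect is `theta`
#' times it; both observed effects carry their reported SEs. The nuisance
#' means are profiled out in closed form and `theta` maximized by 1-D
#' search started at the IVW estimate; the SE comes from the curvature of
#' the profile log-likelihood at the maximum (equal to the observed
#' information for `theta`).
#'
#' @param harmonized Harmonized-instruments data frame (>= 2 usable rows).
#' @param search_halfwidth Half-width of the search interval around the IVW
#'   start value (default 2, widened automatically if the maximum lands on
#'   the boundary).
#' @return One-row estimate tibble (`method = "max_likelihood"`).
#' @export
mr_max_likelihood <- function(harmonized, search_halfwidth = 2) {
  h <- kept_instruments(harmonized)
  check_n_instruments(h, 2, "mr_max_likelihood")
  bx <- h$beta_exp; by <- h$beta_out
  sx2 <- h$se_exp^2; sy2 <- h$se_out^2
  start <- mr_ivw(h, model = "fixed")$beta
  half <- search_halfwidth
  for (attempt in 1:8) {
    opt <- optimize(ml_profile_loglik, interval = c(start - half, start + half),
                    bx = bx, by = by, sx2 = sx2, sy2 = sy2, maximum = TRUE,
                    tol = 1e-10)
    at_edge <- min(abs(opt$maximum - (start + c(-half, half)))) < 1e-6 * half
    if (!at_edge) break
    half <- half * 4
    if (attempt == 8) {
      abort("Maximum-likelihood search failed to bracket the optimum.",
            class = "mrpipe_estimation_error")
    }
  }
  theta <- opt$maximum
  eps <- 1e-5 * max(1, abs(theta))
  curv <- (ml_profile_loglik(theta + eps, bx, by, sx2, sy2) -
             2 * opt$objective +
             ml_profile_loglik(theta - eps, bx, by, sx2, sy2)) / eps^2
  if (!is.finite(curv) || curv >= 0) {
    abort("Non-concave profile likelihood at the optimum.",
          class = "mrpipe_estimation_error")
  }
  se <- sqrt(-1 / curv)
  new_mr_estimate("max_likelihood", theta, se, p_normal(theta, se),
                  nrow(h), "not_applicable")
}

# Orient instruments so every exposure effect is positive (negate both
# betas otherwise); required for the Egger intercept to be interpretable.
orient_positive <- function(h) {
  flip <- h$beta_exp < 0
  h$beta_out[flip] <- -h$beta_out[flip]
  h$beta_exp[flip] <- -h$beta_exp[flip]
  h
}

#' MR-Egger regression and intercept pleiotropy test
#'
#' Weighted least squares of the (positively oriented) outcome effects on
#' the exposure effects with weights `1/se_out^2` and a free intercept. The
#' slope is the pleiotropy-robust causal estimate; a nonzero intercept
#' indicates directional pleiotropy. Analytic SEs use the t-distribution
#' with `J - 2` df; with `bootstrap_reps > 0` the slope/intercept SEs are
#' replaced by the standard deviation over residual-resampled refits (the
#' analytic fit is always reported in `se_analytic`/`intercept_se_analytic`).
#'
#' @param harmonized Harmonized-instruments data frame (>= 3 usable rows).
#' @param bootstrap_reps Number of residual-bootstrap refits (0 = analytic
#'   SEs only).
#' @param seed RNG seed for the bootstrap (required when `bootstrap_reps >
#'   0`).
#' @return One-row estimate tibble (`method = "egger"`) with intercept-test
#'   columns `intercept`, `intercept_se`, `intercept_pvalue` appended.
#' @export
mr_egger <- function(harmonized, bootstrap_reps = 0, seed = NULL) {
  h <- kept_instruments(harmonized)
  check_n_instruments(h, 3, "mr_egger")
  h <- orient_positive(h)
  if (length(unique(h$beta_exp)) == 1L) {
    abort("All exposure effects identical: Egger regressors are collinear.",
          class = "mrpipe_collinearity_error")
  }
  w <- 1 / h$se_out^2
  fit <- lm(beta_out ~ beta_exp, data = h, weights = w)
  cf <- summary(fit)$coefficients
  slope <- cf["beta_exp", "Estimate"]
  slope_se <- cf["beta_exp", "Std. Error"]
  icpt <- cf["(Intercept)", "Estimate"]
  icpt_se <- cf["(Intercept)", "Std. Error"]
  df <- nrow(h) - 2L
  slope_se_final <- slope_se
  icpt_se_final <- icpt_se
  if (bootstrap_reps > 0) {
    if (is.null(seed)) abort("A seed is required for the Egger bootstrap.")
    fitted_y <- fitted(fit)
    res <- h$beta_out - fitted_y
    boots <- with_seed(seed, {
      vapply(seq_len(bootstrap_reps), function(i) {
        idx <- sample.int(nrow(h), replace = TRUE)
        ystar <- fitted_y + res[idx]
        cstar <- coef(lm(ystar ~ h$beta_exp, weights = w))
        c(cstar[2], cstar[1])
      }, numeric(2))
    })
    slope_se_final <- sd(boots[1, ])
    icpt_se_final <- sd(boots[2, ])
  }
  pt2 <- function(est, se) 2 * pt(-abs(est / se), df)
  out <- new_mr_estimate(
    "egger", slope, slope_se_final, pt2(slope, slope_se_final),
    nrow(h), "not_applicable",
    se_analytic = slope_se,
    intercept = icpt,
    intercept_se = icpt_se_final,
    intercept_se_analytic = icpt_se,
    intercept_pvalue = pt2(icpt, icpt_se_final)
  )
  out
}

#' MR-Egger intercept test
#'
#' The intercept, its analytic SE, and two-sided t(J-2) p-value from the
#' Egger fit; the pipeline's pleiotropy gate (p < 0.05 makes Egger the
#' primary estimator).
#'
#' @inheritParams mr_egger
#' @return One-row tibble `intercept`, `se`, `pvalue`.
#' @export
egger_intercept_test <- function(harmonized) {
  e <- mr_egger(harmonized, bootstrap_reps = 0)
  tibble(intercept = e$intercept, se = e$intercept_se,
         pvalue = e$intercept_pvalue)
}

# Weighted median of ratio estimates: sort theta ascending (stable in snp id
# for ties), normalize weights, and interpolate theta linearly across the
# shifted cumulative weights S_j = cumsum(w')_j - w'_j/2 at S = 0.5.
weighted_median_point <- function(theta, w, snp = NULL) {
  o <- if (is.null(snp)) order(theta) else order(theta, snp)
  theta <- theta[o]
  w <- w[o] / sum(w[o])
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  j <- max(which(s < 0.5))
  if (j == length(theta)) return(theta[length(theta)])
  theta[j] + (theta[j + 1] - theta[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

# Parametric-bootstrap SE for (penalized) weighted-median estimators: redraw
# both effect estimates from their sampling distributions and re-estimate.
wm_bootstrap_se <- function(h, reps, seed, penalty = NULL) {
  with_seed(seed, {
    J <- nrow(h)
    bx <- matrix(rnorm(reps * J, mean = rep(h$beta_exp, each = reps),
                       sd = rep(h$se_exp, each = reps)), nrow = reps)
    by <- matrix(rnorm(reps * J, mean = rep(h$beta_out, each = reps),
                       sd = rep(h$se_out, each = reps)), nrow = reps)
    ests <- vapply(seq_len(reps), function(i) {
      theta <- by[i, ] / bx[i, ]
      w <- (bx[i, ] / h$se_out)^2
      if (is.null(penalty)) {
        weighted_median_point(theta, w)
      } else {
        penalized_wm_point(theta, w, penalty)
      }
    }, numeric(1))
    sd(ests)
  })
}

#' Weighted median estimator
#'
#' Consistent when at least half the total weight comes from valid
#' instruments. The point estimate interpolates the sorted per-SNP ratios
#' across cumulative inverse-variance weight at 50%; the SE is a parametric
#' bootstrap over the instruments' sampling distributions.
#'
#' @param harmonized Harmonized-instruments data frame (>= 3 usable rows).
#' @param bootstrap_reps Bootstrap resamples for the SE (default 5000).
#' @param seed RNG seed for the bootstrap.
#' @return One-row estimate tibble (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(harmonized, bootstrap_reps = 5000, seed = 1) {
  h <- kept_instruments(harmonized)
  check_n_instruments(h, 3, "mr_weighted_median")
  rt <- ratio_terms(h)
  beta <- weighted_median_point(rt$theta, rt$w, h$snp)
  se <- wm_bootstrap_se(h, bootstrap_reps, seed)
  new_mr_estimate("weighted_median", beta, se, p_normal(beta, se),
                  nrow(h), "not_applicable")
}

# Penalize each instrument's weight by how strongly its ratio disagrees with
# the plain weighted median: Q_j = w_j (theta_j - theta_WM)^2 referred to
# chi-square(1), w*_j = w_j * min(1, penalty * p_j).
penalized_wm_point <- function(theta, w, penalty) {
  wm <- weighted_median_point(theta, w)
  qj <- w * (theta - wm)^2
  pj <- pchisq(qj, df = 1, lower.tail = FALSE)
  weighted_median_point(theta, w * pmin(1, penalty * pj))
}

#' Penalized weighted median estimator
#'
#' Downweights instruments whose ratio estimates are outlying relative to
#' the plain weighted median (chi-square(1) heterogeneity penalty), then
#' recomputes the weighted median; robust to a minority of invalid
#' instruments.
#'
#' @inheritParams mr_weighted_median
#' @param penalty Penalty constant multiplying each instrument's
#'   heterogeneity p-value (default 20).
#' @return One-row estimate tibble (`method = "penalized_weighted_median"`).
#' @export
mr_penalized_weighted_median <- function(harmonized, penalty = 20,
                                         bootstrap_reps = 5000, seed = 1) {
  h <- kept_instruments(harmonized)
  check_n_instruments(h, 3, "mr_penalized_weighted_median")
  assert_positive(penalty, "penalty")
  rt <- ratio_terms(h)
  beta <- penalized_wm_point(rt$theta, rt$w, penalty)
  se <- wm_bootstrap_se(h, bootstrap_reps, seed, penalty = penalty)
  new_mr_estimate("penalized_weighted_median", beta, se, p_normal(beta, se),
                  nrow(h), "not_applicable")
}

#' Run every applicable estimator on one harmonized instrument set
#'
#' Applies the per-method minimum instrument counts (Wald at J = 1; IVW and
#' maximum likelihood at J >= 2; Egger and the median estimators at J >= 3)
#' and stacks the one-row results.
#'
#' @param harmonized Harmonized-instruments data frame.
#' @param model IVW model selection passed to [mr_ivw()].
#' @param bootstrap_reps Named list of bootstrap sizes
#'   (`median`, `egger`).
#' @param seed RNG seed for all bootstraps.
#' @return Estimate tibble with one row per method run.
#' @export
mr_all_methods <- function(harmonized, model = "auto",
                           bootstrap_reps = list(median = 5000, egger = 1000),
                           seed = 1) {
  h <- kept_instruments(harmonized)
  J <- nrow(h)
  if (J == 0) abort("No usable instruments.", class = "mrpipe_no_instruments")
  if (J == 1) return(wald_ratio(h))
  out <- list(mr_ivw(h, model = model), mr_max_likelihood(h))
  if (J >= 3) {
    egger_try <- tryCatch(
      mr_egger(h, bootstrap_reps = bootstrap_reps$egger, seed = seed),
      mrpipe_collinearity_error = function(e) {
        warn(conditionMessage(e))
        NULL
      }
    )
    out <- c(out, list(
      egger_try,
      mr_weighted_median(h, bootstrap_reps$median, seed),
      mr_penalized_weighted_median(h, bootstrap_reps = bootstrap_reps$median,
                                   seed = seed)
    ))
  }
  res <- bind_rows(purrr::compact(out))
  class(res) <- c("mr_estimate", class(res))
  res
}
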