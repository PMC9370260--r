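test_that("Wald ratio handles signs and degenerate input", {
  expect_equal(wald_ratio(h_table(1, 0.01, 0.5, 0.1))$beta, 0.5)
  expect_equal(wald_ratio(h_table(1, 0.01, 0.5, 0.1))$se, 0.1)
  w <- wald_ratio(h_table(-0.2, 0.01, 0.1, 0.02))
  expect_equal(w$beta, -0.5)
  expect_equal(w$se, 0.1)
  expect_equal(wald_ratio(h_table(0.37, 0.01, 0.37, 0.1))$beta, 1)
  expect_error(wald_ratio(h_table(0, 0.01, 0.5, 0.1)), "beta_exp")
})

test_that("Cochran's Q, I2 and the homogeneous limit", {
  # J = 2, theta = (0, 1), unit ratio weights, beta = 0.5:
  # Q = 1*(0.5)^2 + 1*(0.5)^2 = 0.5
  h <- h_table(c(1, 1), c(0.01, 0.01), c(0, 1), c(1, 1))
  q <- cochran_q(h, 0.5)
  expect_equal(q$q, 0.5)
  expect_equal(q$q_df, 1)
  # identical ratios: Q = 0, I2 = 0, p = 1
  h2 <- h_table(c(0.5, 1), c(0.01, 0.01), c(0.15, 0.3), c(0.1, 0.1))
  q2 <- cochran_q(h2, 0.3)
  expect_equal(q2$q, 0, tolerance = 1e-20)
  expect_equal(q2$i2, 0)
  expect_equal(q2$q_pvalue, 1)
  # I2 never negative
  set.seed(5)
  for (i in 1:20) {
    h3 <- h_table(rnorm(5, 0.1, 0.02), rep(0.01, 5), rnorm(5, 0, 0.1),
                  runif(5, 0.05, 0.2))
    expect_gte(cochran_q(h3, mr_ivw(h3, "fixed")$beta)$i2, 0)
  }
})

test_that("IVW pools homogeneous ratios exactly and gates fixed/random", {
  h <- h_table(c(1, 1), c(0.01, 0.01), c(0.3, 0.3), c(0.1, 0.1))
  e <- mr_ivw(h, "auto")
  expect_equal(e$beta, 0.3)
  expect_equal(e$q, 0)
  expect_equal(e$model, "fixed")
  expect_equal(e$se, 1 / sqrt(2) * 0.1)
  # gross heterogeneity switches auto to random and inflates the SE
  h2 <- h_table(rep(1, 4), rep(0.01, 4), c(-2, -1, 1, 2), rep(0.05, 4))
  e2 <- mr_ivw(h2, "auto")
  expect_equal(e2$model, "random")
  expect_equal(e2$se, mr_ivw(h2, "fixed")$se * sqrt(e2$q / e2$q_df))
  expect_lt(e2$q_pvalue, 0.05)
})

test_that("duplicating the instrument list preserves IVW beta, shrinks SE by sqrt(2)", {
  sim <- simulate_two_sample(sim_config(theta = 0.25, seed = 3))
  h <- sim_h(sim)
  h2 <- dplyr::bind_rows(h, h)
  e1 <- mr_ivw(h, "fixed")
  e2 <- mr_ivw(h2, "fixed")
  expect_equal(e2$beta, e1$beta)
  expect_equal(e2$se, e1$se / sqrt(2))
})

test_that("maximum likelihood matches IVW as exposure noise vanishes", {
  h <- h_table(c(0.08, 0.1, 0.12, 0.09, 0.11), rep(1e-6, 5),
               c(0.02, 0.035, 0.02, 0.04, 0.03), rep(0.012, 5))
  expect_equal(mr_max_likelihood(h)$beta, mr_ivw(h, "fixed")$beta,
               tolerance = 1e-3)
  # homogeneous ratios: the common ratio is recovered
  h2 <- h_table(c(0.5, 1, 2), rep(0.01, 3), c(0.2, 0.4, 0.8), rep(0.1, 3))
  expect_equal(mr_max_likelihood(h2)$beta, 0.4, tolerance = 1e-6)
})

test_that("Egger recovers exact lines and reports the intercept test", {
  bx <- c(0.05, 0.08, 0.1, 0.13, 0.2)
  # noiseless line through the origin
  h <- h_table(bx, rep(0.01, 5), 0.4 * bx, rep(0.05, 5))
  e <- mr_egger(h)
  expect_equal(e$beta, 0.4, tolerance = 1e-12)
  expect_equal(e$intercept, 0, tolerance = 1e-12)
  # noiseless affine line: intercept is the directional pleiotropy
  h2 <- h_table(bx, rep(0.01, 5), 0.05 + 0.4 * bx, rep(0.05, 5))
  e2 <- mr_egger(h2)
  expect_equal(e2$beta, 0.4, tolerance = 1e-10)
  expect_equal(e2$intercept, 0.05, tolerance = 1e-10)
  it <- egger_intercept_test(h2)
  expect_equal(it$intercept, 0.05, tolerance = 1e-10)
  # orientation: negating an instrument's pair of betas changes nothing
  h3 <- h2
  h3$beta_exp[2] <- -h3$beta_exp[2]
  h3$beta_out[2] <- -h3$beta_out[2]
  expect_equal(mr_egger(h3)$beta, e2$beta)
  expect_equal(mr_egger(h3)$intercept, e2$intercept)
  # collinear exposure effects cannot be fit
  h4 <- h_table(rep(0.1, 4), rep(0.01, 4), rnorm(4, 0.04, 0.01),
                rep(0.05, 4))
  expect_error(mr_egger(h4), class = "mrpipe_collinearity_error")
})

test_that("Egger analytic p-values use t with J - 2 df", {
  set.seed(9)
  h <- sim_h(simulate_two_sample(sim_config(theta = 0.25, seed = 14)))
  e <- mr_egger(h)
  tval <- e$beta / e$se
  expect_equal(e$pvalue, 2 * pt(-abs(tval), nrow(h) - 2))
})

test_that("Egger intercept test holds its size under no pleiotropy", {
  reps <- 2000
  p <- vapply(seq_len(reps), function(i) {
    h <- sim_h(simulate_two_sample(sim_config(theta = 0.25, seed = 90000 + i)))
    egger_intercept_test(h)$pvalue
  }, numeric(1))
  # nominal 0.05; allow the binomial-plus-approximation margin up to 0.075
  expect_lte(mean(p < 0.05), 0.075)
})

test_that("Egger beats IVW under directional pleiotropy", {
  # InSIDE holds: direct effects alpha_j ~ N(0.03, 0.01^2) independent of
  # instrument strength; skewed per-SNP R2 gives the strength spread Egger
  # needs; balanced 50k-sample outcome GWAS.
  wins <- vapply(1:200, function(i) {
    h <- sim_h(simulate_two_sample(sim_config(
      n_snps = 20, theta = 0.25, n_out = 50000, case_fraction = 0.5,
      r2_split = "exponential", pleiotropy_mode = "directional",
      pleiotropy_mean = 0.03, pleiotropy_sd = 0.01, seed = 70000 + i
    )))
    abs(mr_egger(h)$beta - 0.25) < abs(mr_ivw(h, "fixed")$beta - 0.25)
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("weighted median interpolates cumulative weight at one half", {
  # equal weights, odd J: the middle ratio
  h <- h_table(c(1, 1, 1), rep(0.01, 3), c(0.1, 0.3, 0.9), rep(0.1, 3))
  expect_equal(mr_weighted_median(h, bootstrap_reps = 50, seed = 1)$beta, 0.3)
  # equal weights equal the sample median for odd J
  set.seed(13)
  th <- rnorm(7)
  h2 <- h_table(rep(1, 7), rep(0.01, 7), th, rep(0.1, 7))
  expect_equal(mr_weighted_median(h2, bootstrap_reps = 50, seed = 1)$beta,
               median(th))
  # dominant weight pins the estimate
  h3 <- h_table(c(7, 1, 1), c(0.01, 0.01, 0.01), c(1.4, 0.9, 1.1),
                c(0.1, 0.7, 0.7)) # w = (4900, ~2, ~2): theta1 = 0.2
  expect_equal(mr_weighted_median(h3, bootstrap_reps = 50, seed = 1)$beta,
               0.2, tolerance = 0.01)
})

test_that("weighted median agrees with a dense grid-scan oracle", {
  set.seed(99)
  for (i in 1:200) {
    J <- 5
    h <- h_table(runif(J, 0.05, 0.3), runif(J, 0.005, 0.02),
                 rnorm(J, 0.1, 0.2), runif(J, 0.02, 0.2))
    theta <- h$beta_out / h$beta_exp
    w <- (h$beta_exp / h$se_out)^2
    o <- order(theta)
    ts <- theta[o]
    ws <- w[o] / sum(w)
    s <- cumsum(ws) - ws / 2
    # dense scan of the cumulative-weight axis via stats::approx, read off
    # at S = 0.5 (independent of the package's manual interpolation)
    grid <- sort(unique(c(seq(0, 1, length.out = 100001), 0.5)))
    scan <- approx(s, ts, xout = grid, rule = 2, ties = "ordered")$y
    oracle <- scan[match(0.5, grid)]
    expect_lt(
      abs(mr_weighted_median(h, bootstrap_reps = 2, seed = 1)$beta - oracle),
      1e-9
    )
  }
})

test_that("penalized weighted median ignores concordant sets, resists outliers", {
  # no outliers: penalty never binds, estimates identical
  sim <- simulate_two_sample(sim_config(theta = 0.25, seed = 31))
  h <- sim_h(sim)
  wm <- mr_weighted_median(h, bootstrap_reps = 50, seed = 2)
  pwm <- mr_penalized_weighted_median(h, bootstrap_reps = 50, seed = 2)
  expect_equal(pwm$beta, wm$beta)
  # one gross outlier ratio: penalized estimate tracks the outlier-free median
  h_out <- h_table(rep(0.1, 10), rep(0.005, 10),
                   c(0.1 * c(0.28, 0.29, 0.30, 0.30, 0.31, 0.32, 0.31, 0.29,
                             0.30), 0.5),
                   rep(0.008, 10))
  clean_wm <- mr_weighted_median(h_out[1:9, ], bootstrap_reps = 50,
                                 seed = 2)$beta
  pwm_out <- mr_penalized_weighted_median(h_out, bootstrap_reps = 50,
                                          seed = 2)$beta
  expect_lt(abs(pwm_out - clean_wm), 0.02)
  # weighted median is scale-invariant in the weights (penalty -> 0 limit)
  theta <- h$beta_out / h$beta_exp
  w <- (h$beta_exp / h$se_out)^2
  expect_equal(mrpipe:::weighted_median_point(theta, w),
               mrpipe:::weighted_median_point(theta, 1e-4 * w))
})

test_that("bootstrap standard errors reproduce bit-for-bit given a seed", {
  h <- sim_h(simulate_two_sample(sim_config(theta = 0.2, seed = 77)))
  a <- mr_weighted_median(h, bootstrap_reps = 200, seed = 42)
  b <- mr_weighted_median(h, bootstrap_reps = 200, seed = 42)
  expect_identical(a$se, b$se)
  expect_false(isTRUE(all.equal(
    a$se, mr_weighted_median(h, bootstrap_reps = 200, seed = 43)$se
  )))
  e1 <- mr_egger(h, bootstrap_reps = 100, seed = 7)
  e2 <- mr_egger(h, bootstrap_reps = 100, seed = 7)
  expect_identical(e1$se, e2$se)
  expect_identical(e1$intercept_se, e2$intercept_se)
  # analytic fit reported alongside the bootstrap
  expect_equal(e1$se_analytic, mr_egger(h)$se)
})

test_that("all estimators are equivariant under exposure rescaling", {
  h <- sim_h(simulate_two_sample(sim_config(theta = 0.25, seed = 55)))
  hs <- scale_exposure(h, 0.1)
  ests <- list(
    function(x) mr_ivw(x, "fixed"),
    mr_max_likelihood,
    function(x) mr_egger(x),
    function(x) mr_weighted_median(x, bootstrap_reps = 100, seed = 5),
    function(x) mr_penalized_weighted_median(x, bootstrap_reps = 100, seed = 5)
  )
  for (f in ests) {
    expect_equal(f(hs)$beta, 0.1 * f(h)$beta, tolerance = 1e-6)
    expect_equal(f(hs)$se, 0.1 * f(h)$se, tolerance = 1e-6)
  }
})

test_that("point estimates are invariant to duplicating the instruments", {
  h <- sim_h(simulate_two_sample(sim_config(theta = 0.25, seed = 56)))
  h2 <- dplyr::bind_rows(h, h)
  h2$snp <- sprintf("rs%03d", seq_len(nrow(h2)))
  expect_equal(mr_ivw(h2, "fixed")$beta, mr_ivw(h, "fixed")$beta)
  expect_equal(mr_max_likelihood(h2)$beta, mr_max_likelihood(h)$beta,
               tolerance = 1e-8)
  expect_equal(mr_egger(h2)$beta, mr_egger(h)$beta)
  # the interpolated median is NOT duplication-invariant (every normalized
  # weight halves, moving the midpoint-offset crossing): counter-example
  # theta = (1, 2), w = (0.3, 0.7) gives 1.7 before and 2.0 after. Document
  # the behaviour rather than asserting a false identity.
  wm1 <- mrpipe:::weighted_median_point(c(1, 2), c(0.3, 0.7))
  wm2 <- mrpipe:::weighted_median_point(c(1, 1, 2, 2), c(0.3, 0.3, 0.7, 0.7))
  expect_equal(wm1, 1.7)
  expect_equal(wm2, 2)
})

test_that("estimators agree on clean strong-instrument data", {
  h <- sim_h(simulate_two_sample(sim_config(theta = 0.25, n_exp = 2e5,
                                            seed = 58)))
  ests <- dplyr::bind_rows(
    mr_ivw(h, "fixed"), mr_max_likelihood(h), mr_egger(h),
    mr_weighted_median(h, bootstrap_reps = 300, seed = 4),
    mr_penalized_weighted_median(h, bootstrap_reps = 300, seed = 4),
    wald_ratio(h[which.max(abs(h$beta_exp / h$se_exp)), ])
  )
  for (i in seq_len(nrow(ests))) {
    for (j in seq_len(nrow(ests))) {
      expect_lt(abs(ests$beta[i] - ests$beta[j]),
                3 * sqrt(ests$se[i]^2 + ests$se[j]^2) + 1e-12)
    }
  }
})

test_that("method dispatcher respects instrument-count gates", {
  sim <- simulate_two_sample(sim_config(theta = 0.2, seed = 61))
  h <- sim_h(sim)
  all5 <- mr_all_methods(h, bootstrap_reps = list(median = 50, egger = 20),
                         seed = 1)
  expect_setequal(all5$method,
                  c("ivw", "max_likelihood", "egger", "weighted_median",
                    "penalized_weighted_median"))
  two <- mr_all_methods(h[1:2, ], seed = 1)
  expect_setequal(two$method, c("ivw", "max_likelihood"))
  one <- mr_all_methods(h[1, ], seed = 1)
  expect_equal(one$method, "wald")
  expect_equal(one$beta, wald_ratio(h[1, ])$beta)
})

test_that("tidy() renders estimates in broom conventions", {
  h <- sim_h(simulate_two_sample(sim_config(theta = 0.2, seed = 62)))
  e <- mr_all_methods(h, bootstrap_reps = list(median = 20, egger = 0),
                      seed = 1)
  td <- tidy(e)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_equal(td$estimate, e$beta)
})
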