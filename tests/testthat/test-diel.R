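# Daily paired means, the diel t-test, the exponential temperature fit and
# the temperature adjustment.

test_that("daily means are plain arithmetic over the period's hours", {
  s <- toy_labeled_series(days = 3, rs_day = 2, rs_night = 3)
  dm <- daily_means(s)
  full <- dm[dm$n_night_hours == 12, ]   # interior dates have whole nights
  expect_true(all(dm$day_mean_rs == 2))
  expect_true(all(dm$night_mean_rs == 3))
  expect_true(all(full$n_day_hours == 12))
  # hand-built asymmetric values
  s2 <- data.frame(period = rep(c("day", "night"), c(3, 3)),
                   diel_date = as.Date("2012-06-05"),
                   rs = c(1, 2, 3, 2, 3, 4), ts = 15)
  dm2 <- daily_means(s2)
  expect_identical(dm2$day_mean_rs, 2)
  expect_identical(dm2$night_mean_rs, 3)
})

test_that("diel test handles identity, constant shift and low n", {
  same <- data.frame(day_mean_rs = rep(2, 30), night_mean_rs = rep(2, 30))
  r <- diel_test(same)
  expect_identical(r$t_stat, 0)
  expect_identical(r$p_value, 1)
  expect_identical(r$class, "ns")
  shift <- data.frame(day_mean_rs = rep(2, 30),
                      night_mean_rs = rep(2.5, 30))
  r2 <- diel_test(shift)
  expect_lt(r2$p_value, 1e-10)
  expect_identical(r2$class, "pos")
  expect_equal(r2$percent_delta, 100 * 0.5 / 2)
  low <- data.frame(day_mean_rs = 1:3, night_mean_rs = 2:4)
  r3 <- diel_test(low)
  expect_identical(r3$class, "ns")
  expect_true(r3$low_n)
})

test_that("SEM of the diel difference matches a bootstrap oracle", {
  set.seed(21)
  d <- rnorm(80, 2, 0.3); n <- d + rnorm(80, 0.2, 0.25)
  r <- diel_test(data.frame(day_mean_rs = d, night_mean_rs = n))
  boot <- replicate(4000, mean(sample(n - d, 80, replace = TRUE)))
  expect_equal(r$sem, stats::sd(boot), tolerance = 0.1)
})

test_that("noiseless exponential data invert exactly", {
  ts <- seq(5, 25, length.out = 60)
  s <- data.frame(rs = 1.5 * exp(0.0693147 * ts), ts = ts)
  fit <- fit_temp_response(s)
  expect_equal(fit$rs0, 1.5, tolerance = 1e-6)
  expect_equal(fit$beta, 0.0693147, tolerance = 1e-6)
  expect_equal(fit$q10, 2, tolerance = 1e-6)
  expect_identical(fit$q10, exp(10 * fit$beta))
  expect_equal(fit$r2, 1)
})

test_that("flat response yields q10 near 1 with a covering interval", {
  set.seed(22)
  ts <- runif(500, 10, 25)
  s <- data.frame(rs = exp(rnorm(500, log(2), 0.1)), ts = ts)
  fit <- fit_temp_response(s)
  expect_equal(fit$q10, 1, tolerance = 0.1)
  ci_beta <- fit$beta + c(-2, 2) * fit$se_beta
  expect_true(ci_beta[1] < 0 && ci_beta[2] > 0)
})

test_that("degenerate fits are refused", {
  s <- data.frame(rs = rexp(50) + 0.1, ts = rep(15, 50))
  expect_error(fit_temp_response(s), "temperature range")
  expect_error(fit_temp_response(s[1:10, ]), "too few hours")
})

test_that("log and nonlinear estimators agree on mildly noisy data", {
  set.seed(23)
  ts <- runif(1500, 8, 28)
  cv <- 0.1; s2 <- log(1 + cv^2)
  s <- data.frame(ts = ts,
                  rs = 0.8 * exp(log(2.5) / 10 * ts) *
                    rlnorm(1500, -s2 / 2, sqrt(s2)))
  f_log <- fit_temp_response(s)
  f_nls <- fit_temp_response(s, method = "nls")
  expect_identical(f_nls$fit_method, "nls")
  expect_lt(abs(f_log$q10 - f_nls$q10) / f_log$q10, 0.05)
  expect_gt(f_log$q10, 2.3); expect_lt(f_log$q10, 2.7)
})

test_that("temperature adjustment: identity at the reference, one decade
           doubles a q10 = 2 flux, and removes a pure Ts artifact", {
  daily <- data.frame(diel_date = as.Date("2012-06-01") + 0:9,
                      day_mean_rs = 1, night_mean_rs = 1,
                      day_mean_ts = 18, night_mean_ts = 8)
  fit2 <- list(q10 = 2)
  adj <- adjust_to_mean_temp(daily, fit2, fit2, ref_ts = 18)
  expect_equal(adj$day_rs_adj, rep(1, 10))     # Ts == ref: unchanged
  expect_equal(adj$night_rs_adj, rep(2, 10))   # one decade up at q10 = 2
  expect_error(adjust_to_mean_temp(daily, NULL, fit2, 18), "required")
})

test_that("adjustment removes the pure Ts-phase artifact across sites", {
  # sites whose only diel asymmetry is the soil-temperature phase: the raw
  # cross-site day-night difference is driven by Ts alone, and the adjusted
  # difference should be indistinguishable from zero in >= 90% of batches.
  # (Within one site the fitted Q10s' estimation error leaves a random
  # offset comparable to the paired-test SEM, so the comparison is made
  # across sites, which is also how the study design pools evidence.)
  site_adjusted_means <- function(seed) {
    st <- generate_site(generator_config(
      gpp_max = 0, base_root = 0, lag_mean = 0, ts_phase_lag = 2,
      noise_cv = 0.1, end_date = "2012-07-31", seed = seed))
    lab <- label_hours(st$series, st$meta)
    dm <- daily_means(lab)
    adj <- adjust_to_mean_temp(dm, fit_temp_response(lab, "day"),
                               fit_temp_response(lab, "night"),
                               site_mean_ts(lab))
    c(day = mean(adj$day_rs_adj), night = mean(adj$night_rs_adj))
  }
  ok <- 0
  for (batch in 1:20) {
    m <- vapply(batch * 100 + 1:6, site_adjusted_means, numeric(2))
    p <- stats::t.test(m["night", ], m["day", ], paired = TRUE)$p.value
    if (p >= 0.05) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.9)
})
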