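# SMA regression and the GPP linkage analyses.

test_that("SMA recovers exact lines and hand-computed slopes", {
  x <- 1:20
  f <- sma_fit(x, 2 * x)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$r, 1)
  expect_equal(f$slope_ci_low, 2)
  expect_equal(f$slope_ci_high, 2)
  g <- sma_fit(c(1, 2, 3), c(6, 4, 2))
  expect_equal(g$slope, -2)    # sign(r) * sd(y)/sd(x) = -1 * 2/1
  expect_equal(g$r, -1)
  expect_error(sma_fit(rep(1, 5), 1:5), "variance")
  expect_error(sma_fit(1:2, 1:2), "3 points")
})

test_that("SMA identities hold on random inputs", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n, 0, sample(c(0.1, 1, 3), 1))
    f <- sma_fit(x, y)
    expect_equal(f$slope, sign(f$r) * sd(y) / sd(x), tolerance = 1e-10)
    # symmetry: slope(y~x) * slope(x~y) = 1
    expect_equal(f$slope * sma_fit(y, x)$slope, 1, tolerance = 1e-10)
    # SMA slope equals OLS slope divided by |r|
    ols <- unname(coef(lm(y ~ x))[2])
    expect_equal(f$slope, ols / abs(f$r), tolerance = 1e-10)
  }
})

test_that("SMA slope estimates the sd ratio in a bivariate normal", {
  set.seed(32)
  n <- 1e4; rho <- 0.8
  x <- rnorm(n)
  y <- 1.5 * (rho * x + sqrt(1 - rho^2) * rnorm(n))
  f <- sma_fit(x, y)
  expect_equal(f$slope, 1.5, tolerance = 0.05 / 1.5)
  expect_true(f$slope_ci_low < 1.5 && f$slope_ci_high > 1.5)
})

test_that("cross-site night-vs-day SMA flags the amplifying night excess", {
  sm <- data.frame(day_mean_rs = c(1, 2, 3), night_mean_rs = c(1, 2, 3))
  f <- day_night_sma(sm)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_error(day_night_sma(sm[1:2, ]), "3 sites")
  set.seed(33)
  batch <- lapply(1:12, function(s) {
    scale <- runif(1, 0.5, 2)
    st <- generate_site(generator_config(
      site_id = sprintf("s%02d", s), seed = 100 + s,
      base_root = 0.04 * scale, base_het = 0.6 * scale,
      end_date = "2012-07-15"))
    lab <- label_hours(st$series, st$meta)
    dm <- daily_means(lab)
    data.frame(day_mean_rs = mean(dm$day_mean_rs),
               night_mean_rs = mean(dm$night_mean_rs))
  })
  f2 <- day_night_sma(do.call(rbind, batch))
  expect_gt(f2$slope, 1)
})

test_that("lag profile finds a constructed 5-day shift exactly", {
  set.seed(34)
  dates <- as.Date("2012-06-01") + 0:199
  gpp <- data.frame(date = dates, gpp_gC_m2_d = 5 + cumsum(rnorm(200)) / 5 +
                      rnorm(200))
  rs <- data.frame(date = dates,
                   rs = gpp$gpp_gC_m2_d[pmax(1, seq_len(200) - 5)])
  rs <- rs[-(1:5), ]
  prof <- gpp_lag_profile(rs, gpp)
  expect_identical(prof$peak_lag, 5L)
  expect_equal(prof$peak_r, 1)
  expect_identical(length(prof$r_by_lag), 46L)
})

test_that("lag profile reports NA where pairs are too few", {
  dates <- as.Date("2012-06-01") + 0:29
  rs <- data.frame(date = dates, rs = rnorm(30, 3))
  gpp <- data.frame(date = dates, gpp_gC_m2_d = rnorm(30, 5))
  prof <- gpp_lag_profile(rs, gpp)
  expect_true(all(is.na(prof$r_by_lag[25:46])))  # < 10 overlapping pairs
})

test_that("daily aggregates of an hourly 8-h lag peak at lag 0 or 1 day", {
  st <- generate_site(generator_config(seed = 35, noise_cv = 0.05))
  lab <- label_hours(st$series, st$meta)
  daily_rs <- aggregate(rs ~ diel_date, lab, mean)
  names(daily_rs) <- c("date", "rs")
  prof <- gpp_lag_profile(daily_rs, st$gpp_daily)
  expect_lte(prof$peak_lag, 1L)
})

test_that("period-specific Rs-GPP fits behave and guard degenerate GPP", {
  st <- generate_site(generator_config(seed = 36))
  lab <- label_hours(st$series, st$meta)
  dm <- daily_means(lab)
  fits <- rs_gpp_sma(dm, st$gpp_daily)
  expect_true(is.finite(fits$day$slope) && is.finite(fits$night$slope))
  # identical day and night fluxes give identical fits
  dm2 <- dm; dm2$night_mean_rs <- dm2$day_mean_rs
  fits2 <- rs_gpp_sma(dm2, st$gpp_daily)
  expect_identical(fits2$day, fits2$night)
  const <- data.frame(date = dm$diel_date,
                      gpp_gC_m2_d = rep(4, nrow(dm)))
  expect_error(rs_gpp_sma(dm, const), "variance")
})
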