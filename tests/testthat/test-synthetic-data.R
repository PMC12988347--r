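# The generator is the ground truth for everything downstream, so its own
# invariants get tested hardest: determinism, component mass balance,
# flattened-driver degeneracy, the sign of the diel difference under the
# lag mechanism, and placement of the substrate-supply kernel.

test_that("identical seeds reproduce identical series bit-for-bit", {
  a <- generate_site(generator_config(seed = 42))
  b <- generate_site(generator_config(seed = 42))
  expect_identical(a$series, b$series)
  c <- generate_site(generator_config(seed = 43))
  expect_false(identical(a$series$rs, c$series$rs))
})

test_that("noise-free series satisfy Rs = Rroot + Rh at every hour", {
  st <- generate_site(generator_config(noise_cv = 0, seed = 7))
  expect_equal(st$series$rs, st$series$rroot + st$series$rh,
               tolerance = 1e-12)
  expect_true(all(st$series$rs >= 0))
  expect_true(all(st$series$rroot >= 0))
  expect_true(all(st$series$rh >= 0))
})

test_that("flattened drivers give a constant flux with equal diel means", {
  st <- generate_site(generator_config(
    noise_cv = 0, lag_mean = 0, priming_coef = 0, gpp_max = 0,
    beta_root = 0, beta_het = 0, seed = 1))
  expect_equal(diff(range(st$series$rs)), 0)
  lab <- label_hours(st$series, st$meta)
  dm <- daily_means(lab)
  expect_equal(dm$day_mean_rs, dm$night_mean_rs)
})

test_that("with no lag and warm days, warm-period mean flux exceeds night", {
  # pure heterotrophic response, Ts peak shortly after noon: monotone
  # exponential makes the warmer day the larger flux
  st <- generate_site(generator_config(
    noise_cv = 0, lag_mean = 0, gpp_max = 0, base_root = 0,
    ts_phase_lag = 2, beta_het = log(2) / 10, seed = 1))
  lab <- label_hours(st$series, st$meta)
  dm <- daily_means(lab)
  expect_true(all(dm$day_mean_ts > dm$night_mean_ts))
  expect_true(all(dm$day_mean_rs > dm$night_mean_rs))
})

test_that("an 8-h substrate lag elevates nighttime over daytime flux,
           matching a 1-min-resolution integration of the same equations", {
  cfg <- generator_config(noise_cv = 0, gpp_day_cv = 0, ts_phase_lag = 2,
                          seed = 5)
  st <- generate_site(cfg)
  lab <- label_hours(st$series, st$meta)
  dm <- daily_means(lab)
  expect_gt(mean(dm$night_mean_rs), mean(dm$day_mean_rs))
  orc <- oracle_generator_day_night(phase = 2)
  expect_gt(orc$night_mean, orc$day_mean)
  # hourly generator vs minute-resolution oracle on the period means
  expect_equal(mean(st$series$rs[lab$period == "day"]), orc$day_mean,
               tolerance = 0.03)
  expect_equal(mean(st$series$rs[lab$period == "night"]), orc$night_mean,
               tolerance = 0.03)
})

test_that("substrate kernel has unit mass and the configured mean", {
  k <- dielflux:::substrate_kernel(8, 12)
  expect_equal(sum(k), 1)
  expect_equal(sum((0:48) * k), 8, tolerance = 0.1)
  expect_identical(dielflux:::substrate_kernel(0, 12)[1], 1)
})

test_that("temperature-detrended flux cross-correlates with GPP at the lag", {
  cfg <- generator_config(noise_cv = 0, gpp_day_cv = 0, base_het = 0,
                          priming_coef = 0, seed = 3)
  st <- generate_site(cfg)
  detr <- st$series$rs / exp(cfg$beta_root * st$series$ts)   # = base_root * S
  gpp <- st$series$gpp
  cc <- sapply(0:24, function(l) {
    n <- length(gpp)
    stats::cor(detr[(l + 1):n], gpp[1:(n - l)])
  })
  expect_lte(abs(which.max(cc) - 1 - cfg$lag_mean), 1)
})

test_that("ground truth records exact component Q10 and the diel sign", {
  cfg <- generator_config(beta_root = 0.05, beta_het = 0.12, seed = 2)
  st <- generate_site(cfg)
  expect_identical(st$truth$true_Q10_root, exp(10 * 0.05))
  expect_identical(st$truth$true_Q10_het, exp(10 * 0.12))
  expect_true(st$truth$expected_sign_dRs %in% c(-1, 0, 1))
})

test_that("generated files round-trip losslessly through the reader", {
  st <- generate_site(generator_config(seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_cosore_like(st, dir)
  meta <- read_site_meta(paths[["meta"]])
  expect_identical(meta$site_id, st$meta$site_id)
  rec <- read_flux_table(paths[["flux"]], meta)
  rec <- select_depth(rec)
  expect_equal(rec$rs, st$series$rs, tolerance = 1e-12)
  expect_equal(rec$ts, st$series$ts, tolerance = 1e-12)
  expect_identical(attr(rec, "depth_used_ts"), 5)
  expect_error(write_cosore_like(list(series = st$series[0, ],
                                      meta = st$meta), dir),
               "empty")
})

test_that("a multi-site batch is deterministic file-by-file", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (s in 1:3) {
    cfg <- generator_config(site_id = sprintf("s%02d", s), seed = s,
                            end_date = "2012-06-20")
    write_cosore_like(generate_site(cfg), d1)
    write_cosore_like(generate_site(cfg), d2)
  }
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
  # distinct seeds give distinct flux files
  flux <- grep("flux", f1, value = TRUE)
  expect_false(identical(readLines(flux[1]), readLines(flux[2])))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(noise_cv = -1))
  expect_error(generator_config(end_date = "2012-05-01"))
  expect_error(generator_config(lag_mean = -2))
})
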