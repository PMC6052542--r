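test_that("noiseless generation recovers configured targets exactly", {
  cfg <- synthetic_reactor_config(noise_cv = 0)
  s <- generate_reactor_series(cfg)
  m <- performance_metrics(s)
  steady <- m[m$time_day >= cfg$acclimation$duration_days, ]
  expect_equal(steady$mcfa_conversion, rep(17.7, nrow(steady)),
               tolerance = 1e-9)
  expect_equal(steady$scfa_conversion, rep(20.4, nrow(steady)),
               tolerance = 1e-9)
  expect_equal(steady$carbohydrate_conversion, rep(97, nrow(steady)),
               tolerance = 1e-9)
  expect_equal(steady$cod_removed, rep(9.1, nrow(steady)), tolerance = 1e-9)
})

test_that("the same seed generates byte-identical series", {
  cfg <- synthetic_reactor_config(noise_cv = 0.05, seed = 7)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_series_csv(generate_reactor_series(cfg), f1)
  write_series_csv(generate_reactor_series(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  cfg2 <- synthetic_reactor_config(noise_cv = 0.05, seed = 8)
  f3 <- tempfile(fileext = ".csv")
  write_series_csv(generate_reactor_series(cfg2), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
  unlink(c(f1, f2, f3))
})

test_that("noisy generation recovers targets within sampling error", {
  cfg <- synthetic_reactor_config(noise_cv = 0.02, seed = 42)
  s <- generate_reactor_series(cfg)
  ss <- steady_state_summary(performance_metrics(s), c(30, 252))
  expect_equal(ss$n, 38)
  se <- 17.7 * 0.02 / sqrt(ss$n)
  expect_lt(abs(ss$mean[["mcfa_conversion"]] - 17.7), 3 * se)
  expect_lt(abs(ss$mean[["scfa_conversion"]] - 20.4), 3 * 20.4 * 0.02 / sqrt(ss$n))
  # estimator bias shrinks with many sampling points
  cfg_big <- synthetic_reactor_config(noise_cv = 0.10, seed = 11,
                                      duration_days = 3000,
                                      sampling_interval_days = 6)
  sbig <- generate_reactor_series(cfg_big)
  ssb <- steady_state_summary(performance_metrics(sbig), c(30, 3000))
  expect_lt(abs(ssb$mean[["mcfa_conversion"]] - 17.7),
            3 * 17.7 * 0.10 / sqrt(ssb$n))
})

test_that("odd-chain acids rise then fall during acclimation only", {
  s <- generate_reactor_series(synthetic_reactor_config(noise_cv = 0))
  m <- performance_metrics(s)
  early <- m$ocfa_fraction[m$time_day <= 24]
  expect_gt(max(early, na.rm = TRUE), 5)           # visible early pulse
  expect_equal(m$ocfa_fraction[m$time_day >= 30],
               rep(0, sum(m$time_day >= 30)))       # gone at steady state
})

test_that("generated feed closes: identified components + unknown = total", {
  for (feed in list(stillage_batch1(), stillage_batch2())) {
    expect_equal(sum(feed$components$value), feed$total_soluble_cod,
                 tolerance = 1e-12, info = feed$batch_id)
  }
})

test_that("invalid generator targets are rejected", {
  expect_error(synthetic_reactor_config(
    targets = list(scfa_conversion = 0.6, mcfa_conversion = 0.5,
                   carbohydrate_conversion = 0.9,
                   hexanoate_octanoate_cod_ratio = 9,
                   acetic_share_of_scfa = 0.3)
  ), "mass balance")
  expect_error(synthetic_reactor_config(noise_cv = -0.1), "noise_cv")
})

test_that("series and feed CSV round-trip through the readers", {
  cfg <- synthetic_reactor_config(noise_cv = 0.02, seed = 3)
  s <- generate_reactor_series(cfg)
  fs <- tempfile(fileext = ".csv"); ff <- tempfile(fileext = ".csv")
  write_series_csv(s, fs)
  write_feed_csv(stillage_batch1(), ff)
  feed <- read_feed_csv(ff)
  expect_equal(feed$total_soluble_cod, 95400)
  expect_equal(feed$total_carbohydrate, 40100)
  s2 <- read_series_csv(fs, feed, srt = 6)
  m1 <- steady_state_summary(performance_metrics(s), c(30, 252))
  m2 <- steady_state_summary(performance_metrics(s2), c(30, 252))
  expect_equal(m1$mean, m2$mean, tolerance = 1e-9)
  unlink(c(fs, ff))
})

test_that("scenario generation applies overrides and re-validates", {
  sc <- generate_tea_scenario()
  expect_s3_class(sc, "tea_scenario")
  expect_equal(unname(sc$conversions$fractions),
               c(0.054, 0.15, 0.16, 0.017))
  over <- generate_tea_scenario(list(
    conversions = list(fractions = c(acetic = 0.054, butyric = 0.15,
                                     hexanoic = 0, octanoic = 0.017))
  ))
  b <- biorefinery_balance(over)
  expect_equal(b$recovered$mass_kg_h[b$recovered$compound == "hexanoic"], 0)
  expect_error(generate_tea_scenario(list(
    conversions = list(fractions = c(acetic = 0.6, butyric = 0.4,
                                     hexanoic = 0.2, octanoic = 0))
  )), "> 1")
})

test_that("scenarios round-trip through YAML", {
  sc <- generate_tea_scenario()
  tmp <- tempfile(fileext = ".yaml")
  write_scenario(sc, tmp)
  sc2 <- read_scenario(tmp)
  expect_equal(sc2$conversions$fractions, sc$conversions$fractions)
  expect_equal(sc2$financial$indirect_multiplier,
               sc$financial$indirect_multiplier)
  expect_equal(sum(scale_equipment_cost(sc2$capex)),
               sum(scale_equipment_cost(sc$capex)))
  unlink(tmp)
})
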