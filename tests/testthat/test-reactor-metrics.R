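# Minimal hand-built series: one feed, explicit sample rows.
make_series <- function(samples, feed = stillage_batch1(), srt = 6) {
  reactor_series(samples, feed, srt)
}

test_that("a sample identical to the feed with no acids scores zero on all metrics", {
  feed <- stillage_batch1()
  s <- make_series(data.frame(
    time_day = c(10, 10),
    compound = c("total_soluble_cod", "total_carbohydrate"),
    value = c(feed$total_soluble_cod, feed$total_carbohydrate)
  ))
  m <- performance_metrics(s)
  expect_equal(m$cod_removed, 0)
  expect_equal(m$carbohydrate_conversion, 0)
  expect_equal(m$scfa_conversion, 0)
  expect_equal(m$mcfa_conversion, 0)
})

test_that("conversion metrics reproduce hand-computed percentages", {
  # feed carbs 40,100 mg COD/L; residual 1,203 -> 97.0% converted
  # hexanoate 15,296 mg COD/L over feed COD 95,600 -> 16.0% to MCFA
  feed <- feed_reference("f", data.frame(compound = "xylose", value = 20800),
                         total_soluble_cod = 95600,
                         total_carbohydrate = 40100)
  s <- make_series(data.frame(
    time_day = 50,
    compound = c("total_soluble_cod", "total_carbohydrate", "hexanoic"),
    value = c(80000, 1203, 15296)
  ), feed = feed)
  m <- performance_metrics(s)
  expect_equal(m$carbohydrate_conversion, 100 * (40100 - 1203) / 40100)
  expect_equal(round(m$carbohydrate_conversion, 1), 97.0)
  expect_equal(m$mcfa_conversion, 100 * 15296 / 95600)
  expect_equal(round(m$mcfa_conversion, 1), 16.0)
})

test_that("metrics are invariant to rescaling all concentrations", {
  feed1 <- stillage_batch1()
  k <- 3.7
  comp2 <- feed1$components; comp2$value <- comp2$value * k
  feed2 <- feed_reference("scaled", comp2, feed1$total_soluble_cod * k,
                          feed1$total_carbohydrate * k)
  samples <- data.frame(
    time_day = 40,
    compound = c("total_soluble_cod", "total_carbohydrate",
                 "acetic", "butyric", "hexanoic", "octanoic"),
    value = c(86000, 2500, 5100, 14000, 15000, 1600)
  )
  scaled <- samples; scaled$value <- scaled$value * k
  m1 <- performance_metrics(make_series(samples, feed1))
  m2 <- performance_metrics(make_series(scaled, feed2))
  expect_equal(m1, m2)
})

test_that("negative conversions from noise are retained, not truncated", {
  feed <- stillage_batch1()
  s <- make_series(data.frame(
    time_day = 60,
    compound = "total_soluble_cod",
    value = feed$total_soluble_cod * 1.05   # measured above feed
  ))
  expect_lt(performance_metrics(s)$cod_removed, 0)
})

test_that("samples are compared against the feed batch active at their time", {
  s <- reactor_series(
    data.frame(time_day = c(100, 150),
               compound = "total_soluble_cod",
               value = c(95400, 95800)),
    list(stillage_batch1(), stillage_batch2()), srt = 6,
    batch_switch_day = 120
  )
  m <- performance_metrics(s)
  expect_equal(m$cod_removed, c(0, 0))   # each matches its own batch exactly
})

test_that("steady-state summary gives window mean and sample SD", {
  records <- data.frame(time_day = c(10, 30, 40, 50),
                        mcfa_conversion = c(99, 16, 18, 20))
  ss <- steady_state_summary(records, c(30, 252))
  expect_equal(unname(ss$mean["mcfa_conversion"]), 18)
  expect_equal(unname(ss$sd["mcfa_conversion"]), 2)  # hand: sd of {16,18,20}
  expect_equal(ss$n, 3)
  expect_error(steady_state_summary(records, c(300, 400)), "available")
  const <- data.frame(time_day = c(30, 60), x = c(18, 18))
  sc <- steady_state_summary(const, c(30, 252))
  expect_equal(unname(sc$mean["x"]), 18)
  expect_equal(unname(sc$sd["x"]), 0)
})

test_that("productivity and titer follow the CSTR steady-state chain", {
  # 15.6 g COD/L held at SRT 6 d -> 2.6 g COD/L/d; titer fraction via ThOD
  feed <- stillage_batch1()
  s <- make_series(data.frame(
    time_day = c(40, 60), compound = "hexanoic", value = c(15600, 15600)
  ), feed = feed)
  pt <- productivity_and_titer(s, "hexanoic")
  expect_equal(pt$productivity_g_cod_per_L_day, 2.6)
  expect_equal(pt$basis, "COD")
  expect_equal(pt$titer_fraction_pct,
               100 * 15.6 / cod_factor("hexanoic") / 10.8)
  # identity: titer_fraction = 100 * productivity * SRT / (thod * solubility)
  expect_equal(pt$titer_fraction_pct,
               titer_fraction_from_productivity(
                 pt$productivity_g_cod_per_L_day, 6, "hexanoic"))
  # hand chain for octanoate: 0.27 * 6 / 2.441 / 0.68
  expect_equal(titer_fraction_from_productivity(0.27, 6, "octanoic"),
               100 * 0.27 * 6 / cod_factor("octanoic") / 0.68)
  # zero concentration gives zero productivity and titer
  s0 <- make_series(data.frame(time_day = c(40, 60), compound = "hexanoic",
                               value = c(0, 0)), feed = feed)
  pt0 <- productivity_and_titer(s0, "hexanoic")
  expect_equal(pt0$productivity_g_cod_per_L_day, 0)
  expect_equal(pt0$titer_fraction_pct, 0)
})

test_that("titer fraction warns when solubility is unregistered", {
  feed <- stillage_batch1()
  s <- make_series(data.frame(time_day = c(40, 60), compound = "acetic",
                              value = c(5000, 5000)), feed = feed)
  expect_warning(pt <- productivity_and_titer(s, "acetic"), "solubility")
  expect_true(is.na(pt$titer_fraction_pct))
})

test_that("feed characterization reproduces the fermentation arithmetic", {
  fc <- feed_characterization()
  expect_equal(fc$xylose_consumed_pct, 100 * (36000 - 19000) / 36000)
  expect_equal(round(fc$xylose_consumed_pct), 47)
  expect_gt(fc$glucose_consumed_pct, 99.9)
  expect_equal(fc$stillage_cod_fraction_pct,
               100 * mean(c(95400, 95800)) / 160000)
  expect_equal(fc$residual_ethanol_pct, 100 * mean(c(1220, 1590)) / 51000)
  expect_lt(fc$residual_ethanol_pct, 3)
})

test_that("raw-mass CSV values convert to COD at ingestion", {
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_day = 1, compound = "hexanoic",
                       value = 1000, unit = "mg_per_L", sd = 10),
            tmp, row.names = FALSE)
  df <- read_concentration_csv(tmp)
  expect_equal(df$value, 1000 * cod_factor("hexanoic"))
  expect_equal(df$unit, "mg_COD_per_L")
  unlink(tmp)
})
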