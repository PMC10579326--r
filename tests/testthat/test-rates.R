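series_df <- function(times, excess) data.frame(time_h = times, excess = excess)

test_that("collinear points give the closed-form slope with p at zero", {
  ser <- series_df(c(0, 6, 12, 24), c(0, 1, 2, 4))
  res <- suppressWarnings(fit_linear_rate(ser))
  expect_equal(res$slope, 4.0)            # 1/6 nmol L^-1 h^-1
  expect_equal(res$r_squared, 1.0)
  expect_lt(res$p_one_sided, 1e-12)
  expect_identical(res$df, 2L)
})

test_that("a flat series is insignificant with zero slope", {
  ser <- series_df(c(0, 6, 12, 24), rep(0, 4))
  res <- fit_linear_rate(ser)
  expect_equal(res$slope, 0)
  expect_equal(res$p_one_sided, 1)
  res <- classify_rate(res, ser, labelling_fraction = 1)
  expect_identical(res$kinetic_class, "insignificant")
  expect_equal(res$net_rate, 0)
})

test_that("OLS agrees with a normal-equations oracle to 1e-10", {
  set.seed(11)
  for (i in 1:25) {
    t_h <- c(0, 6, 12, 24)
    y <- rnorm(4, mean = 0.02 * t_h, sd = 0.05)
    res <- fit_linear_rate(series_df(t_h, y))
    orc <- ols_oracle(t_h / 24, y)
    expect_equal(res$slope, orc$slope, tolerance = 1e-10)
    expect_equal(res$slope_se, orc$se, tolerance = 1e-10)
    expect_equal(res$r_squared, orc$r2, tolerance = 1e-10)
    expect_equal(res$p_one_sided, orc$p, tolerance = 1e-10)
  }
})

test_that("late-onset production is classed exponential with zero net rate", {
  ser <- series_df(c(0, 6, 12, 24), c(0, 0, 0, 2))
  res <- classify_rate(fit_linear_rate(ser), ser, labelling_fraction = 1)
  expect_identical(res$kinetic_class, "exponential")
  expect_equal(res$net_rate, 0)
})

test_that("labelling fraction scales the net rate of significant fits", {
  set.seed(3)
  t_h <- c(0, 6, 12, 24)
  y <- 0.5 / 24 * t_h + rnorm(4, sd = 0.002)
  ser <- series_df(t_h, y)
  raw <- fit_linear_rate(ser)
  mpn <- classify_rate(raw, ser, labelling_fraction = 1)
  dic <- classify_rate(raw, ser, labelling_fraction = 0.10)
  expect_identical(mpn$kinetic_class, "linear_significant")
  expect_equal(dic$net_rate, 10 * mpn$net_rate)
  expect_equal(mpn$net_rate, mpn$slope)
})

test_that("negative slopes are never significant or reported as consumption", {
  ser <- series_df(c(0, 6, 12, 24), c(0, -0.1, -0.22, -0.41))
  res <- classify_rate(fit_linear_rate(ser), ser, labelling_fraction = 1)
  expect_identical(res$kinetic_class, "insignificant")
  expect_equal(res$net_rate, 0)
  expect_gt(res$p_one_sided, 0.5)
})

test_that("net rate is invariant to common rescaling of the excess", {
  set.seed(8)
  t_h <- c(0, 6, 12, 24)
  y <- 0.4 / 24 * t_h + rnorm(4, sd = 0.01)
  r1 <- classify_rate(fit_linear_rate(series_df(t_h, y)),
                      series_df(t_h, y), labelling_fraction = 1)
  scl <- 7.3
  r2 <- classify_rate(fit_linear_rate(series_df(t_h, y * scl)),
                      series_df(t_h, y * scl), labelling_fraction = 1,
                      detection_sd = 0.01 * scl)
  expect_equal(r2$net_rate, scl * r1$net_rate, tolerance = 1e-12)
  expect_identical(r1$kinetic_class, r2$kinetic_class)
  expect_equal(r1$p_one_sided, r2$p_one_sided, tolerance = 1e-12)
})

test_that("simulated linear incubations recover their true rate", {
  set.seed(21)
  for (r in c(0.06, 0.4, 1.3)) {
    cfg <- simulation_config(true_rate = r, noise_sd_excess = 0.03 * r)
    nets <- replicate(120, {
      rec <- simulate_incubation(cfg)
      ser <- excess_13c_series(rec)
      classify_rate(fit_linear_rate(ser), ser)$net_rate
    })
    passed <- nets[nets > 0]
    expect_gte(length(passed) / length(nets), 0.8)
    expect_lt(abs(stats::median(passed) - r) / r, 0.10)
  }
})

test_that("carbon fixation follows the isotope uptake formula", {
  expect_equal(carbon_fixation_rate(20, 1.08, 1.58, 5.08, 1), 2.5)
  expect_equal(carbon_fixation_rate(20, 1.08, 1.08, 5.08, 1), 0)
  expect_equal(carbon_fixation_rate(20, 1.08, 1.58, 5.08, 2), 1.25)
  expect_error(carbon_fixation_rate(20, 1.08, 1.58, 1.0, 1),
               "invalid labelling")
  expect_warning(neg <- carbon_fixation_rate(20, 1.08, 1.02, 5.08, 1),
                 "negative")
  expect_true(attr(neg, "negative_rate"))
})

test_that("estimate_rates returns one tidy row per incubation", {
  set.seed(5)
  recs <- list(make_linear_record(0.4, noise = 0.02),
               make_linear_record(1.3, noise = 0.02))
  tab <- estimate_rates(recs)
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("station", "depth_category", "treatment", "replicate",
                    "slope", "p_one_sided", "r_squared", "kinetic_class",
                    "net_rate") %in% names(tab)))
  expect_true(all(tab$df == 2L))
})
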