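test_that("headspace fraction follows equilibrium partitioning", {
  expect_equal(headspace_fraction(vessel_geometry(
    liquid_volume = 0.2, headspace_volume = 0.05,
    partition_coefficient = 0)), 1.0)
  expect_equal(headspace_fraction(vessel_geometry(
    liquid_volume = 0.05, headspace_volume = 0.05,
    subsample_volume = 0.005, partition_coefficient = 1)), 0.5)
  expect_equal(headspace_fraction(vessel_geometry(
    liquid_volume = 0.2, headspace_volume = 0.05,
    partition_coefficient = 0.032)), 0.05 / (0.05 + 0.0064),
    tolerance = 1e-12)
})

test_that("invalid geometries are rejected", {
  expect_error(vessel_geometry(liquid_volume = -1), "positive")
  expect_error(vessel_geometry(subsample_volume = 0.06), "smaller")
  expect_error(vessel_geometry(partition_coefficient = -0.1), ">= 0")
})

test_that("dilution correction factors match event-by-event removal", {
  g0 <- vessel_geometry(partition_coefficient = 0)  # f_g = 1
  d <- dilution_correction_factors(g0, 3)
  expect_equal(d[1], 1.0)
  expect_equal(d[3], (1 / 0.9)^2, tolerance = 1e-12)
  # f_g = 0.5: one event removes 5% of the total
  g5 <- vessel_geometry(liquid_volume = 0.2, headspace_volume = 0.05,
                        subsample_volume = 0.005,
                        partition_coefficient = 0.25)
  expect_equal(headspace_fraction(g5), 0.5)
  expect_equal(dilution_correction_factors(g5, 2)[2], 1 / 0.95,
               tolerance = 1e-12)
  expect_true(all(diff(dilution_correction_factors(g0, 6)) > 0))
})

test_that("delta-13C conversion is monotone and inverts to 1e-12", {
  d <- seq(-120, 5000, by = 7)
  x <- d13c_to_atom_fraction(d)
  expect_true(all(diff(x) > 0))
  expect_true(all(x > 0 & x < 1))
  expect_equal(atom_fraction_to_d13c(x), d, tolerance = 1e-12)
})

test_that("no enrichment yields an all-zero excess series", {
  m <- data.frame(time_h = c(0, 6, 12, 24, 48),
                  ch4_nmol_headspace = c(5, 4.8, 4.6, 4.4, 4.2),
                  atom_fraction_13c = rep(0.0110566, 5))
  rec <- incubation_record("S1", "surface", "MPn", "A", vessel_geometry(),
                           1, m)
  expect_equal(excess_13c_series(rec)$excess, rep(0, 5))
})

test_that("malformed series are rejected with specific errors", {
  g <- vessel_geometry()
  m <- data.frame(time_h = c(0, 12, 6), ch4_nmol_headspace = c(5, 5, 5),
                  atom_fraction_13c = rep(0.011, 3))
  expect_error(incubation_record("S1", "surface", "MPn", "A", g, 1, m),
               "strictly increasing")
  m2 <- data.frame(time_h = c(6, 12, 24), ch4_nmol_headspace = c(5, 5, 5),
                   atom_fraction_13c = rep(0.011, 3))
  expect_error(incubation_record("S1", "surface", "MPn", "A", g, 1, m2),
               "baseline")
})

test_that("zero-noise round trip is the identity for any solubility", {
  for (k_h in c(0, 0.032, 0.3, 1)) {
    for (rate in c(0.06, 1.3)) {
      rec <- make_linear_record(rate = rate, k_h = k_h)
      ser <- excess_13c_series(rec)
      expect_equal(ser$excess, attr(rec, "truth")$true_excess,
                   tolerance = 1e-12)
      expect_equal(ser$excess[1], 0)
    }
  }
  # irregular subsampling schedule
  rec <- make_linear_record(rate = 0.7, k_h = 0.5,
                            schedule = c(0, 3, 7, 20, 30, 55))
  expect_equal(excess_13c_series(rec)$excess,
               attr(rec, "truth")$true_excess, tolerance = 1e-12)
})

test_that("mass balance conserves tracer to 1e-9 relative", {
  rec <- make_linear_record(rate = 1.0, k_h = 0.032)
  ser <- excess_13c_series(rec)
  vl <- rec$geometry$liquid_volume
  total <- (attr(ser, "vessel_excess_nmol") +
              attr(ser, "removed_excess_nmol")) / vl
  produced <- attr(rec, "truth")$true_excess
  expect_equal(total[-1], produced[-1], tolerance = 1e-9)
})

test_that("ppm conversion follows the ideal gas law", {
  # 1 ppm in 1 L at 0 C, 1 atm: 1e-6 * 101325e-3/(8.3145*273.15) mol
  expect_equal(ppm_to_nmol(1, 1, 0),
               1e-6 * 101325e-3 / (8.314462618 * 273.15) * 1e9,
               tolerance = 1e-12)
  # ~1.9 ppm in a 50 mL headspace at 27 C is a few nmol
  expect_true(ppm_to_nmol(1.9, 0.05, 27) > 3 &&
                ppm_to_nmol(1.9, 0.05, 27) < 5)
})
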