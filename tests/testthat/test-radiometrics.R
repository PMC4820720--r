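test_that("ingrowth fraction follows the daughter half-life", {
  nc <- nuclide_constants()
  expect_equal(ingrowth_fraction(0), 0)
  expect_equal(ingrowth_fraction(nc$halflife_y90_hr), 0.5)
  # a fortnight after separation the daughter is near equilibrium
  expect_equal(ingrowth_fraction(336), 1 - 2^(-336 / 64.05),
               tolerance = 1e-12)
  expect_gt(ingrowth_fraction(336), 0.97)
  expect_error(ingrowth_fraction(-1), "since separation")
  t <- seq(0, 500, by = 7)
  g <- ingrowth_fraction(t)
  expect_true(all(diff(g) > 0))
  expect_true(all(g < 1))
})

test_that("forward rate model hits its closed-form anchors", {
  calib0 <- assay_calibration(background_rate = 0)
  # blank sample: background only
  expect_equal(expected_gross_rate(0, 100, 24), 0.155)
  # 1 Bq at secular equilibrium, reference thickness, no background
  # (parent decay suppressed to isolate the equilibrium limit 2A)
  stable_parent <- nuclide_constants(halflife_sr90_yr = 1e9)
  expect_equal(expected_gross_rate(1, 1e5, 24, calib0, stable_parent),
               60 * 0.339 * 2, tolerance = 1e-6)
  # parent decay over a fortnight shifts the rate by under 0.1%
  r14 <- expected_gross_rate(1, 336, 24, calib0)
  no_decay <- 60 * 0.339 * 1 * (1 + ingrowth_fraction(336))
  expect_lt(r14, no_decay)
  expect_equal(r14, no_decay, tolerance = 1e-3)
})

test_that("ingrowth fit recovers the generating activity exactly on
           noiseless series", {
  t <- c(24, 72, 120, 200, 280, 336)
  ser <- make_series(0.05, t, rep(720, 6))
  fit <- fit_ingrowth_series(ser, 24)
  expect_equal(fit$activity_at_separation, 0.05, tolerance = 1e-8)
  expect_equal(fit$goodness_of_fit_p, 1, tolerance = 1e-6)
  expect_false(fit$below_detection)
  # round trip holds for other activities, thicknesses and yields
  for (a in c(0.002, 0.2, 3)) {
    ser <- make_series(a, t, rep(360, 6), thickness = 30)
    fit <- fit_ingrowth_series(ser, 30, yield = 0.7)
    expect_equal(fit$activity_at_separation, a / 0.7, tolerance = 1e-6 * a)
  }
})

test_that("goodness of fit flags a series that does not grow in", {
  t <- c(24, 72, 120, 200, 280, 336)
  grow <- make_series(0.05, t, rep(720, 6))
  flat_rate <- mean(grow$gross_counts / grow$duration_min)
  flat <- data.frame(t_hours = t, duration_min = 720,
                     gross_counts = flat_rate * 720)
  fit <- fit_ingrowth_series(flat, 24)
  expect_lt(fit$goodness_of_fit_p, 0.05)
})

test_that("ingrowth fit refuses degenerate input", {
  ser <- make_series(0.05, c(24, 72), c(720, 720))
  expect_error(fit_ingrowth_series(ser, 24), "insufficient")
  expect_error(fit_ingrowth_series(make_series(0.05, c(24, 72, 120),
                                               rep(720, 3)), 24, yield = 0),
               "yield")
})

test_that("equilibrium activity applies the full correction chain", {
  calib <- assay_calibration()
  expect_equal(as.numeric(equilibrium_activity(1.0, 24, 0.70, calib)),
               (1 / 60) / (2 * 0.339 * 0.70), tolerance = 1e-12)
  expect_equal(as.numeric(equilibrium_activity(0, 24, 0.70, calib)), 0)
  a1 <- as.numeric(equilibrium_activity(2.5, 24, 0.4, calib))
  a2 <- as.numeric(equilibrium_activity(2.5, 24, 0.8, calib))
  expect_equal(a1 / a2, 2)
  neg <- equilibrium_activity(-0.3, 24, 0.7, calib)
  expect_equal(as.numeric(neg), 0)
  expect_true(attr(neg, "below_background"))
  expect_error(equilibrium_activity(1, 24, 0, calib), "yield")
})

test_that("equilibrium count and forward model are mutually consistent", {
  # at equilibrium (before parent decay) the net rate is 60*eff*f*2*A*y,
  # and the activity reconstruction must invert it for any A, f, yield
  calib <- assay_calibration()
  stable_parent <- nuclide_constants(halflife_sr90_yr = 1e9)
  for (a in c(0.01, 0.4, 7)) {
    for (y in c(0.5, 0.7, 0.96)) {
      gross <- expected_gross_rate(a * y, 1e5, 28, calib, stable_parent)
      back <- as.numeric(equilibrium_activity(gross - calib$background_rate,
                                              28, y, calib))
      expect_equal(back, a, tolerance = 1e-6)
    }
  }
})

test_that("self-absorption factor is normalised at the standard
           thickness", {
  expect_equal(self_absorption_factor(24, 0.01), 1)
  expect_equal(self_absorption_factor(100, 0), 1)
  x <- seq(5, 60, by = 5)
  f <- self_absorption_factor(x, 0.008)
  expect_true(all(diff(f) < 0))
  expect_error(self_absorption_factor(-2, 0.01), "thickness")
})

test_that("absorption coefficient is recovered from calibration pairs", {
  x <- c(5, 10, 20, 30, 40)
  expect_equal(fit_absorption_curve(x, exp(-0.01 * x)), 0.01,
               tolerance = 1e-8)
  expect_error(fit_absorption_curve(c(20, 20, 20), c(0.8, 0.81, 0.79)),
               "distinct")
  expect_error(fit_absorption_curve(x, exp(0.01 * x)), "calibration error")
  # noisy round trip at the standard thickness stays within 1%
  set.seed(7)
  r <- exp(-0.006 * x) * (1 + rnorm(length(x), 0, 0.005))
  mu <- fit_absorption_curve(x, pmin(r, 1))
  expect_equal(self_absorption_factor(24, mu),
               self_absorption_factor(24, 0.006), tolerance = 0.01)
})

test_that("decay correction to the reference date composes and matches
           closed forms", {
  nc <- nuclide_constants()
  ref <- nc$reference_date
  expect_equal(decay_correct_to_reference(1, ref), 1)
  one_half <- ref + round(28.8 * 365.25)
  expect_equal(decay_correct_to_reference(1, one_half), 2, tolerance = 1e-4)
  two_yr <- ref + round(2 * 365.25)
  expect_equal(decay_correct_to_reference(1, two_yr),
               exp(log(2) * 2 / 28.8), tolerance = 1e-4)
  expect_error(decay_correct_to_reference(1, ref - 1), "precedes")
  # correcting t1 -> t0 equals t1 -> t2 -> t0
  t1 <- ref + 900
  t2 <- ref + 400
  direct <- decay_correct_to_reference(1, t1)
  nc2 <- nuclide_constants(reference_date = t2)
  via <- decay_correct_to_reference(decay_correct_to_reference(1, t1, nc2),
                                    t2)
  expect_equal(direct, via, tolerance = 1e-12)
})

test_that("background sigma reproduces the counter's quoted statistics", {
  s <- background_sigma(0.155, 720)
  expect_equal(s, 0.0147, tolerance = 0.01)
  expect_equal(round(3 * s, 3), 0.044)
  expect_equal(background_sigma(0, 720), 0)
  expect_equal(background_sigma(0.155, 720) /
                 background_sigma(0.155, 4 * 720), 2)
  expect_error(background_sigma(0.155, 0), "duration")
})

test_that("detection limit arithmetic and scaling laws hold", {
  dl <- detection_limit(yield = 0.70, ash_mass_g = 1, ca_fraction = 0.313)
  expect_equal(dl$rate_limit_cpm, 0.044, tolerance = 1e-2)
  expect_equal(dl$activity_limit_mbq, 1.55, tolerance = 1e-2)
  expect_equal(dl$limit_mbq_per_g_ca, 4.94, tolerance = 1e-2)
  base <- detection_limit(yield = 0.5, ash_mass_g = 1, ca_fraction = 0.3)
  doubled <- detection_limit(yield = 1.0, ash_mass_g = 2, ca_fraction = 0.3)
  expect_equal(base$limit_mbq_per_g_ca / doubled$limit_mbq_per_g_ca, 4,
               tolerance = 1e-10)
  quad <- detection_limit(count_duration = 4 * 720, yield = 0.5,
                          ash_mass_g = 1, ca_fraction = 0.3)
  expect_equal(base$limit_mbq_per_g_ca / quad$limit_mbq_per_g_ca, 2,
               tolerance = 1e-10)
  expect_error(detection_limit(ca_fraction = 0), "positive")
})

test_that("blank series rarely exceed the 3-sigma detection limit", {
  set.seed(101)
  calib <- assay_calibration()
  t <- c(24, 72, 120, 200, 280, 336)
  n_rep <- 500
  yield <- 0.7
  limit_bq <- detection_limit(yield = yield, ca_fraction = NULL,
                              count_duration = 720)$activity_limit_mbq / 1000
  exceed <- vapply(seq_len(n_rep), function(i) {
    counts <- rpois(length(t), calib$background_rate * 720)
    ser <- data.frame(t_hours = t, duration_min = 720,
                      gross_counts = counts)
    fit <- fit_ingrowth_series(ser, 24, yield = yield, calib = calib)
    fit$activity_at_separation > limit_bq
  }, logical(1))
  expect_lte(mean(exceed), 0.01)
})
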