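test_that("developmental staging matches the radiographic picture of the
           herd", {
  herd <- cattle_table()
  accident <- as.Date("2011-03-11")
  # the 51-month-old adult: every window closed
  adult <- herd[herd$animal_id == "L-adult-2", ]
  stages <- stage_at_date(development_windows()$tooth_class,
                          adult$birth_date, accident)
  expect_true(all(stages == "complete"))
  # the 8-month-old young animal: premolars early or not yet started
  young <- herd[herd$animal_id == "H-young-2", ]
  p_stages <- stage_at_date(c("P1", "P2", "P3"), young$birth_date, accident)
  expect_true(all(p_stages %in% c("early", "not_started")))
  # and its deciduous molars are finished
  dm_stages <- stage_at_date(c("DM1", "DM2", "DM3"), young$birth_date,
                             accident)
  expect_true(all(dm_stages == "complete"))
  # a query before the window opens
  expect_equal(stage_at_date("P1", as.Date("2012-01-01"),
                             as.Date("2012-06-01")), "not_started")
  expect_error(stage_at_date("XX", accident, accident), "unknown tooth")
})

test_that("predicted specific activity is the time-weighted step mean", {
  step <- exposure_step(10, 100, as.Date("2011-03-11"))
  w <- development_windows()
  # window entirely before the step (deciduous molar of an older animal)
  birth_old <- as.Date("2008-01-01")
  expect_equal(predicted_specific_activity(step, "DM1", birth_old), 10)
  # window entirely after the step (premolar of a calf born at the step)
  expect_equal(predicted_specific_activity(step, "P1",
                                           as.Date("2011-03-11")), 100)
  # straddling windows agree with numerical integration of the step
  birth <- as.Date("2010-07-08")
  for (tc in c("M1", "M2", "M3")) {
    wi <- w[w$tooth_class == tc, ]
    step_age <- as.numeric(step$step_date - birth) / 30.4375
    f <- function(a) ifelse(a < step_age, step$pre_level, step$post_level)
    quad <- stats::integrate(f, wi$start_months, wi$end_months,
                             subdivisions = 2000L, rel.tol = 1e-10)$value /
      (wi$end_months - wi$start_months)
    expect_equal(predicted_specific_activity(step, tc, birth), quad,
                 tolerance = 1e-6)
  }
  # monotone in the post level when part of the window is post-step
  p1 <- predicted_specific_activity(exposure_step(10, 50), "M2", birth)
  p2 <- predicted_specific_activity(exposure_step(10, 200), "M2", birth)
  expect_gt(p2, p1)
})

test_that("class ordering follows the chronology under a rising step", {
  step <- exposure_step(10, 100)
  birth <- as.Date("2010-07-08")   # 8 months old at the step
  pred <- sapply(development_windows()$tooth_class, function(tc)
    predicted_specific_activity(step, tc, birth))
  grp <- substr(names(pred), 1, 1)
  means <- tapply(pred, factor(grp, levels = c("D", "M", "P")), mean)
  expect_true(means[["D"]] < means[["M"]])
  expect_true(means[["M"]] < means[["P"]])
  # an animal developed long before the step is flat across classes
  pred_adult <- sapply(development_windows()$tooth_class, function(tc)
    predicted_specific_activity(step, tc, as.Date("2006-11-27")))
  expect_true(all(abs(pred_adult - 10) < 1e-12))
})

test_that("step recovery inverts the model", {
  birth <- as.Date("2010-07-08")
  w <- development_windows()
  obs <- data.frame(
    tooth_class = w$tooth_class,
    birth_date = birth,
    specific_activity = sapply(w$tooth_class, function(tc)
      predicted_specific_activity(exposure_step(25, 480), tc, birth))
  )
  est <- recover_step(obs)
  expect_equal(est$pre_level, 25, tolerance = 1e-9)
  expect_equal(est$post_level, 480, tolerance = 1e-9)
  # adult dentition: every phi is zero, the step is unidentifiable
  obs_adult <- obs
  obs_adult$birth_date <- as.Date("2005-01-01")
  obs_adult$specific_activity <- 25
  expect_error(recover_step(obs_adult), "unidentifiable")
})

test_that("step recovery is accurate under 10% biological noise", {
  set.seed(21)
  birth <- as.Date("2010-07-08")
  w <- development_windows()
  truth <- sapply(w$tooth_class, function(tc)
    predicted_specific_activity(exposure_step(25, 480), tc, birth))
  rel_err <- replicate(200, {
    obs <- data.frame(tooth_class = w$tooth_class, birth_date = birth,
                      specific_activity = truth *
                        exp(rnorm(length(truth), 0, 0.1)))
    est <- recover_step(obs)
    abs(est$post_level / 480 - 1)
  })
  expect_lt(stats::median(rel_err), 0.15)
})
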