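test_that("model-implied targets match closed forms", {
  still <- list(p_loc_met = 0, p_loc_death = 0, p_met_death = 0)
  sched <- data.frame(time = c(1, 5, 20),
                      quantity = "overall_survival")
  expect_equal(simulate_targets(still, sched), rep(1, 3))

  dying <- list(p_loc_met = 0, p_loc_death = 0.1, p_met_death = 0)
  expect_equal(
    simulate_targets(dying, data.frame(time = 5,
                                       quantity = "overall_survival")),
    0.9^5
  )
  no_mets <- list(p_loc_met = 0, p_loc_death = 0.05, p_met_death = 0.5)
  mf <- simulate_targets(
    no_mets,
    data.frame(time = c(3, 7), quantity = "metastasis_free")
  )
  expect_equal(mf, 0.95^c(3, 7))
})

test_that("non-cycle times interpolate linearly", {
  dying <- list(p_loc_met = 0, p_loc_death = 0.1, p_met_death = 0)
  v <- simulate_targets(dying, data.frame(time = 4.5,
                                          quantity = "overall_survival"))
  expect_equal(v, (0.9^4 + 0.9^5) / 2)
})

test_that("calibration is self-consistent when initialised at the truth", {
  truth <- transition_set(data.frame(
    subgroup = "high_risk", management = "surveillance",
    p_loc_met = 0.08, p_loc_death = 0.02, p_met_death = 0.25
  ))
  sched <- expand.grid(time = c(5, 10, 15),
                       quantity = c("overall_survival", "metastasis_free"),
                       stringsAsFactors = FALSE)
  targets <- generate_calibration_targets(truth, sched, noise_sd = 0,
                                          seed = 2)
  fit <- calibrate_transitions(
    targets, n_starts = 1, seed = 9,
    init = list("high_risk surveillance" = c(0.08, 0.02, 0.25))
  )
  expect_lt(fit$objective, 1e-10)
  expect_equal(fit$transitions$p_loc_met, 0.08, tolerance = 1e-6)
})

test_that("parameters are recovered from noiseless targets under multi-start", {
  truth <- transition_set(data.frame(
    subgroup = "intermediate_risk", management = "surveillance",
    p_loc_met = 0.04, p_loc_death = 0.012, p_met_death = 0.2
  ))
  sched <- expand.grid(time = c(5, 10, 15),
                       quantity = c("overall_survival", "metastasis_free"),
                       stringsAsFactors = FALSE)
  targets <- generate_calibration_targets(truth, sched, noise_sd = 0,
                                          seed = 7)
  fit <- calibrate_transitions(targets, n_starts = 10, seed = 11)
  expect_true(fit$converged)
  expect_lt(abs(fit$transitions$p_loc_met - 0.04), 1e-3)
  expect_lt(abs(fit$transitions$p_loc_death - 0.012), 1e-3)
  expect_lt(abs(fit$transitions$p_met_death - 0.2), 1e-3)
})

test_that("underdetermined calibration is flagged", {
  targets <- calibration_targets(
    subgroup = "low_risk", management = "surveillance",
    time = 5, quantity = "overall_survival", value = 0.9
  )
  fit <- calibrate_transitions(targets, n_starts = 3, seed = 4)
  expect_true(fit$diagnostics$underdetermined)
  expect_equal(fit$diagnostics$n_targets, 1L)
  expect_lt(fit$objective, 1e-8)
})

test_that("degenerate calibration inputs error", {
  t0 <- calibration_targets("low_risk", "surveillance", 5,
                            "overall_survival", 0.9)
  expect_error(calibration_targets("low_risk", "surveillance", -1,
                                   "overall_survival", 0.9))
  expect_error(calibration_targets("low_risk", "surveillance", 5,
                                   "overall_survival", 1.2))
  t0$weight <- 0
  expect_error(calibrate_transitions(t0), "weights")
})

test_that("noisy target generation is reproducible and clamped", {
  truth <- transition_set(data.frame(
    subgroup = "low_risk", management = "surveillance",
    p_loc_met = 0.01, p_loc_death = 0.005, p_met_death = 0.15
  ))
  sched <- data.frame(time = c(5, 10), quantity = "overall_survival")
  a <- generate_calibration_targets(truth, sched, noise_sd = 0.01, seed = 3)
  b <- generate_calibration_targets(truth, sched, noise_sd = 0.01, seed = 3)
  expect_identical(a, b)
  noiseless <- generate_calibration_targets(truth, sched, noise_sd = 0,
                                            seed = 3)
  expect_false(identical(a$value, noiseless$value))
  expect_true(all(a$value >= 0 & a$value <= 1))
})
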