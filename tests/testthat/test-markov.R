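unit_utility <- function() {
  utility_model(baseline = 1, age_slope = 0, metastatic_decrement = 0,
                tpmb_decrement = 0)
}

long_econ <- function(...) {
  econ_settings(start_age = 65, max_age = 465, ...)
}

test_that("discount factors follow the closed form", {
  expect_equal(discount_factor(10, 0), 1)
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(10, 0.035), 1.035^-10)
  expect_equal(discount_factor(10, 0.035), 0.70892, tolerance = 1e-5)
  expect_error(discount_factor(-1, 0.035), "non-negative")
})

test_that("constant-hazard life expectancy matches the geometric closed form", {
  tr <- list(p_loc_met = 0, p_loc_death = 0.1, p_met_death = 0)
  undisc <- run_cohort(tr, unit_utility(), cost_model(),
                       long_econ(discount_costs = 0, discount_effects = 0),
                       model = "cancer")
  expect_equal(undisc$qalys, 1 / 0.1, tolerance = 1e-9)
  disc <- run_cohort(tr, unit_utility(), cost_model(), long_econ(),
                     model = "cancer")
  expect_equal(disc$qalys, 1 / (1 - 0.9 / 1.035), tolerance = 1e-9)
})

test_that("a cohort starting dead accrues nothing", {
  tr <- list(p_loc_met = 0.1, p_loc_death = 0.1, p_met_death = 0.3)
  r <- run_cohort(tr, unit_utility(), cost_model(), econ_settings(),
                  model = "cancer",
                  init = c(localised = 0, metastatic = 0, dead = 1))
  expect_equal(r$qalys, 0)
  expect_equal(r$costs, 0)
})

test_that("occupancy is conserved and death is absorbing", {
  tr <- list(p_loc_met = 0.05, p_loc_death = 0.02, p_met_death = 0.25)
  r <- run_cohort(tr, unit_utility(), cost_model(), econ_settings(),
                  model = "cancer",
                  background_mortality = gompertz_mortality())
  expect_true(all(abs(rowSums(r$trace) - 1) < 1e-9))
  expect_true(all(diff(r$trace[, "dead"]) >= -1e-12))
  expect_true(all(r$trace >= -1e-12))
})

test_that("discounted outcomes are non-increasing in the discount rate", {
  tr <- list(p_loc_met = 0.05, p_loc_death = 0.02, p_met_death = 0.25)
  qalys <- vapply(c(0, 0.015, 0.035, 0.06), function(rate) {
    run_cohort(tr, unit_utility(), cost_model(),
               long_econ(discount_effects = rate), model = "cancer")$qalys
  }, numeric(1))
  expect_true(all(diff(qalys) < 0))
})

test_that("lifetime outcomes vanish when utilities are zero", {
  bundle <- small_bundle()
  bundle$utilities <- utility_model(baseline = 0, age_slope = 0,
                                    metastatic_decrement = 0,
                                    tpmb_decrement = 0)
  d <- execute_strategy(parse_strategy_label("P4 2"), bundle$performance,
                        bundle$prevalence)
  lt <- lifetime_outcomes(d, bundle$transitions, bundle$utilities,
                          bundle$costs, bundle$econ,
                          background_mortality = bundle$mortality)
  expect_equal(lt$total_qalys, 0)
})

test_that("for an all-healthy cohort, lifetime QALYs do not depend on biopsy routing", {
  bundle <- small_bundle()
  bundle$prevalence <- subgroup_prevalence(1, 0, 0, 0)
  totals <- vapply(c("T1 2", "M7 222", "T4 1"), function(label) {
    d <- execute_strategy(parse_strategy_label(label), bundle$performance,
                          bundle$prevalence)
    lifetime_outcomes(d, bundle$transitions, bundle$utilities, bundle$costs,
                      bundle$econ,
                      background_mortality = bundle$mortality)$total_qalys
  }, numeric(1))
  expect_equal(unname(totals[2]), unname(totals[1]), tolerance = 1e-12)
  expect_equal(unname(totals[3]), unname(totals[1]), tolerance = 1e-12)
  # a TPMB-using strategy differs only by the one-off TPMB decrement
  d_p4 <- execute_strategy(parse_strategy_label("P4 2"), bundle$performance,
                           bundle$prevalence)
  lt_p4 <- lifetime_outcomes(d_p4, bundle$transitions, bundle$utilities,
                             bundle$costs, bundle$econ,
                             background_mortality = bundle$mortality)
  expect_equal(lt_p4$total_qalys,
               unname(totals[1]) -
                 bundle$utilities$tpmb_decrement * expected_tpmb_count(d_p4),
               tolerance = 1e-12)
})

test_that("with a treatment benefit, higher sensitivity never lowers QALYs", {
  bundle <- small_bundle()
  # M7 2 2 x: lowering the cut-off increases sensitivity with the same tests
  labels <- sprintf("M7 22%d", 5:2)
  res <- run_base_case(bundle, strategies = labels)
  expect_true(all(diff(res$sensitivity) > 0))
  expect_true(all(diff(res$qalys) > -1e-12))
})

test_that("missing transition rows are reported", {
  bundle <- small_bundle()
  d <- execute_strategy(parse_strategy_label("T1 1"), bundle$performance,
                        bundle$prevalence)
  broken <- bundle$transitions[bundle$transitions$management !=
                                 "surveillance", ]
  expect_error(
    lifetime_outcomes(d, transition_set(broken), bundle$utilities,
                      bundle$costs, bundle$econ),
    "no transition set"
  )
})

test_that("management follows the diagnosis rule", {
  expect_equal(management_for("high_risk", "CS_dx"), "radical_treatment")
  expect_equal(management_for("intermediate_risk", "no_cancer_dx"),
               "surveillance")
  expect_equal(management_for("low_risk", "nonCS_dx"), "surveillance")
  expect_equal(management_for("no_cancer", "no_cancer_dx"), "none")
})
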