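test_that("M7 222 reproduces the published referral probabilities", {
  d <- execute_strategy(parse_strategy_label("M7 222"), packaged_perf(),
                        toy_prevalence())
  rates <- referral_rates(d)
  expect_equal(rates["intermediate_risk", "p_biopsy"], 0.98)
  expect_equal(rates["low_risk", "p_biopsy"], 0.92)
  expect_equal(rates["no_cancer", "p_biopsy"], 0.93)
  expect_equal(rates["high_risk", "p_biopsy"], 1.00)
})

test_that("M7 222 detection in intermediate-risk men matches hand propagation", {
  # refer 0.98; first MRI-targeted TRUSB (type 4, def 2) detects CS with 0.74;
  # the 0.26 without a CS result get a type-5 rebiopsy detecting with 0.87
  d <- execute_strategy(parse_strategy_label("M7 222"), packaged_perf(),
                        toy_prevalence())
  p_cs <- sum(d$prob[d$subgroup == "intermediate_risk" &
                       d$diagnosis == "CS_dx"])
  expect_equal(p_cs, 0.98 * (0.74 + 0.26 * 0.87), tolerance = 1e-12)
})

test_that("the reference-standard strategy is the identity on truth", {
  d <- execute_strategy(parse_strategy_label("P1 1"), packaged_perf(),
                        toy_prevalence())
  expect_equal(strategy_sensitivity(d), 1)
  expect_equal(strategy_specificity(d), 1)
  expect_equal(sum(d$prob[d$subgroup == "low_risk" &
                            d$diagnosis == "nonCS_dx"]), 1)
  rates <- referral_rates(d)
  expect_equal(rates$p_biopsy, rep(1, 4))
})

test_that("strategies whose undetected men terminate in TPMB are perfectly sensitive", {
  prev <- toy_prevalence()
  for (label in c("P4 2", "P2 1", "P7 113", "N1 222", "N4 125", "N7 222")) {
    d <- execute_strategy(parse_strategy_label(label), packaged_perf(), prev)
    expect_identical(strategy_sensitivity(d), 1, label = label)
  }
})

test_that("M7 222 detects every high-risk cancer (cut-off >=2 refers all of them)", {
  d <- execute_strategy(parse_strategy_label("M7 222"), packaged_perf(),
                        subgroup_prevalence(0, 0, 0, 1))
  expect_equal(strategy_sensitivity(d), 1)
})

test_that("blind biopsies give zero sensitivity", {
  d <- execute_strategy(parse_strategy_label("T1 1"), blind_biopsy_table(),
                        toy_prevalence())
  expect_equal(strategy_sensitivity(d), 0)
})

test_that("expected testing cost matches hand propagation for cancer-free men", {
  # M7 222 in cancer-free men: MPMRI for all; 0.93 referred; the first biopsy
  # is always negative so the rebiopsy always triggers: 1.86 TRUSBs expected
  prev <- subgroup_prevalence(1, 0, 0, 0)
  d <- execute_strategy(parse_strategy_label("M7 222"), packaged_perf(), prev)
  m <- 420
  b <- 333
  expect_equal(expected_testing_cost(d, c(MPMRI = m, TRUSB = b, TPMB = 0)),
               m + 1.86 * b, tolerance = 1e-12)
  expect_equal(expected_testing_cost(d, c(MPMRI = 0, TRUSB = 0, TPMB = 0)), 0)
  expect_error(expected_testing_cost(d, c(MPMRI = -1, TRUSB = 0, TPMB = 0)),
               "non-negative")
  p1 <- execute_strategy(parse_strategy_label("P1 2"), packaged_perf(),
                         toy_prevalence())
  expect_equal(expected_testing_cost(p1, c(MPMRI = 9, TRUSB = 9, TPMB = 777)),
               777)
})

test_that("diagnosis severity: CS beats nonCS beats NC along a path", {
  # T3: first TRUSB finds non-CS, type-3 rebiopsy may upgrade to CS
  d <- execute_strategy(parse_strategy_label("T3 1"), packaged_perf(),
                        subgroup_prevalence(0, 0, 1, 0))
  p_cs <- sum(d$prob[d$subgroup == "intermediate_risk" &
                       d$diagnosis == "CS_dx"])
  expect_equal(p_cs, 0.34 + 0.42 * 0.25, tolerance = 1e-12)
})

test_that("propagation conserves probability on random tables", {
  prev <- toy_prevalence()
  strategies <- lapply(c("M7 222", "T9 215", "P6 113", "N3 124", "T4 2"),
                       parse_strategy_label)
  for (seed in 1:5) {
    perf <- random_perf_table(seed)
    for (s in strategies) {
      d <- execute_strategy(s, perf, prev)
      totals <- tapply(d$prob, d$subgroup, sum)
      expect_true(all(abs(totals - 1) < 1e-9))
    }
  }
})

test_that("appending a terminal TPMB never lowers detection in any subgroup", {
  prev <- toy_prevalence()
  for (seed in 1:3) {
    perf <- random_perf_table(seed)
    for (variant in c("222", "125")) {
      m <- execute_strategy(parse_strategy_label(paste("M7", variant)),
                            perf, prev)
      n <- execute_strategy(parse_strategy_label(paste("N7", variant)),
                            perf, prev)
      expect_identical(strategy_sensitivity(n), 1)
      for (sg in subgroup_levels()) {
        expect_gte(sum(n$prob[n$subgroup == sg & n$diagnosis == "CS_dx"]),
                   sum(m$prob[m$subgroup == sg & m$diagnosis == "CS_dx"]) -
                     1e-12)
      }
    }
  }
})

test_that("raising the MPMRI cut-off never increases biopsy referral", {
  prev <- toy_prevalence()
  for (combo in c("M7", "M2", "T7")) {
    digits <- if (combo == "T7") "22" else "22"
    rates <- sapply(2:5, function(co) {
      s <- parse_strategy_label(sprintf("%s %s%d", combo, digits, co))
      referral_rates(execute_strategy(s, packaged_perf(), prev))$p_biopsy
    })
    for (row in seq_len(nrow(rates))) {
      expect_true(all(diff(rates[row, ]) <= 1e-12),
                  label = paste(combo, "subgroup", row))
    }
  }
})

test_that("the microsimulation oracle is deterministic under a fixed seed", {
  s <- parse_strategy_label("M7 222")
  m1 <- microsim_oracle(s, packaged_perf(), toy_prevalence(), n = 2000,
                        seed = 5)
  m2 <- microsim_oracle(s, packaged_perf(), toy_prevalence(), n = 2000,
                        seed = 5)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
})

test_that("the microsimulation agrees exactly with propagation on a degenerate table", {
  d <- execute_strategy(parse_strategy_label("P1 1"), packaged_perf(),
                        toy_prevalence())
  m <- microsim_oracle(parse_strategy_label("P1 1"), packaged_perf(),
                       toy_prevalence(), n = 500, seed = 3)
  expect_identical(strategy_sensitivity(m), 1)
  expect_identical(strategy_specificity(m), 1)
  expect_equal(m$prob, d$prob[match(
    paste(m$subgroup, m$diagnosis), paste(d$subgroup, d$diagnosis))])
})

test_that("microsimulated sensitivity converges to the exact value", {
  s <- parse_strategy_label("M7 222")
  prev <- toy_prevalence()
  d <- execute_strategy(s, packaged_perf(), prev)
  m <- microsim_oracle(s, packaged_perf(), prev, n = 1e5, seed = 42)
  z <- microsim_sensitivity_z(d, m, prev)
  expect_lte(abs(z), 3)
})
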