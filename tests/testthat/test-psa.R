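test_that("moment matching reproduces the stated mean", {
  par <- beta_moment_match(0.9, lower = 0.86, upper = 0.94)
  expect_equal(unname(par[1] / sum(par)), 0.9, tolerance = 1e-6)
  expect_error(beta_moment_match(0.5, sd = 0.6), "variance")
})

test_that("distribution means equal the point estimates", {
  bundle <- small_bundle()
  spec <- assign_distributions(bundle, ess = 100, cost_cv = 0.3,
                               probability_ess = 200)
  set.seed(1)
  n <- 2000
  draws <- replicate(n, draw_parameter_set(spec)$performance[
    "MPMRI|NA|2|2|NA|intermediate_risk", "p_cs"])
  p <- bundle$performance["MPMRI|NA|2|2|NA|intermediate_risk", "p_cs"]
  se <- sqrt(p * (1 - p) / (100 + 1) / n)
  expect_lt(abs(mean(draws) - p), 3 * se)
})

test_that("degenerate specs reproduce the point estimates exactly", {
  bundle <- small_bundle()
  spec <- assign_distributions(bundle, ess = Inf, cost_cv = 0,
                               probability_ess = Inf)
  expect_true(spec$degenerate)
  drawn <- draw_parameter_set(spec)
  expect_equal(as.data.frame(drawn$performance),
               as.data.frame(bundle$performance))
  expect_identical(drawn$unit_costs, bundle$unit_costs)
  expect_error(assign_distributions(bundle, ess = 0), "positive")
})

test_that("structural zeros survive the Dirichlet perturbation", {
  bundle <- small_bundle()
  spec <- assign_distributions(bundle, ess = 20)
  set.seed(8)
  drawn <- draw_parameter_set(spec)
  zero <- as.matrix(bundle$performance[, c("p_nc", "p_noncs", "p_cs")]) == 0
  drawn_probs <- as.matrix(drawn$performance[, c("p_nc", "p_noncs", "p_cs")])
  expect_true(all(drawn_probs[zero] == 0))
  # and perfect specificity survives
  d <- execute_strategy(parse_strategy_label("M7 222"), drawn$performance,
                        drawn$prevalence)
  expect_identical(strategy_specificity(d), 1)
})

test_that("a degenerate PSA equals the deterministic run in every simulation", {
  bundle <- small_bundle()
  spec <- assign_distributions(bundle, ess = Inf, cost_cv = 0,
                               probability_ess = Inf)
  strategies <- resolve <- lapply(c("M7 222", "P4 2"), parse_strategy_label)
  samples <- run_psa(spec, strategies, n = 4, seed = 2, effect = "detection")
  det <- vapply(strategies, function(s) {
    v <- evaluate_strategy(s, bundle, effect = "detection")
    v$effect
  }, numeric(1))
  for (s in 1:4) expect_equal(unname(samples$effect[s, ]), unname(det))
})

test_that("PSA draws are bit-identical under the same seed", {
  bundle <- small_bundle()
  spec <- assign_distributions(bundle)
  s1 <- run_psa(spec, parse_strategy_label("M7 222"), n = 10, seed = 7,
                effect = "detection")
  s2 <- run_psa(spec, parse_strategy_label("M7 222"), n = 10, seed = 7,
                effect = "detection")
  expect_identical(s1$cost, s2$cost)
  expect_identical(s1$effect, s2$effect)
})

test_that("CEAC values partition the simulations and the CEAF picks the best expected strategy", {
  bundle <- small_bundle()
  spec <- assign_distributions(bundle)
  samples <- run_psa(spec, lapply(c("M7 222", "T1 2", "P4 2"),
                                  parse_strategy_label),
                     n = 60, seed = 3, effect = "qaly")
  cc <- ceac_ceaf(samples, thresholds = c(13000, 20000, 30000))
  for (th in unique(cc$threshold)) {
    expect_equal(sum(cc$ceac[cc$threshold == th]), 1)
    expect_equal(sum(cc$on_ceaf[cc$threshold == th]), 1)
    # CEAF value never exceeds the pointwise maximum of the CEACs
    expect_lte(cc$ceac[cc$threshold == th & cc$on_ceaf],
               max(cc$ceac[cc$threshold == th]))
  }
})

test_that("a single strategy is cost-effective with probability one", {
  bundle <- small_bundle()
  spec <- assign_distributions(bundle)
  samples <- run_psa(spec, parse_strategy_label("T1 1"), n = 5, seed = 1,
                     effect = "detection")
  cc <- ceac_ceaf(samples, thresholds = 1000)
  expect_equal(cc$ceac, 1)
  fp <- frontier_probability(samples)
  expect_equal(fp$p_frontier, 1)
})

test_that("the CEAC crossing matches the analytic break-even threshold", {
  # two strategies with fixed effects and normal cost differences:
  # at the break-even threshold the CEAC of each is 0.5
  n <- 4000
  set.seed(21)
  e <- c(A = 0.5, B = 0.4)
  cost_a <- stats::rnorm(n, 1500, 200)
  cost_b <- stats::rnorm(n, 1000, 200)
  samples <- structure(
    list(cost = cbind(A = cost_a, B = cost_b),
         effect = cbind(A = rep(e[["A"]], n), B = rep(e[["B"]], n)),
         labels = c("A", "B"), n = n, seed = 21, effect_type = "qaly"),
    class = "psa_samples"
  )
  break_even <- (1500 - 1000) / (0.5 - 0.4)
  cc <- ceac_ceaf(samples, thresholds = break_even)
  se <- sqrt(0.25 / n)
  expect_lt(abs(cc$ceac[cc$label == "A"] - 0.5), 3 * se)
})

test_that("degenerate frontier probabilities match the deterministic frontier", {
  bundle <- small_bundle()
  spec <- assign_distributions(bundle, ess = Inf, cost_cv = 0,
                               probability_ess = Inf)
  labels <- c("M7 222", "T1 2", "P4 2", "M1 125")
  samples <- run_psa(spec, lapply(labels, parse_strategy_label), n = 3,
                     seed = 5, effect = "detection")
  fp <- frontier_probability(samples)
  expect_true(all(fp$p_frontier %in% c(0, 1)))
  expect_equal(fp$p_frontier == 1, fp$mean_frontier)
  expect_true(all(fp$classification %in% c("frontier", "never")))
  # a frontier always exists in every simulation
  expect_gte(sum(fp$p_frontier), 1)
})

test_that("frontier probabilities converge to their long-run values", {
  bundle <- small_bundle()
  spec <- assign_distributions(bundle, ess = 50)
  labels <- c("M7 222", "T1 2", "P4 2")
  strategies <- lapply(labels, parse_strategy_label)
  short <- frontier_probability(
    run_psa(spec, strategies, n = 120, seed = 13, effect = "detection"))
  long <- frontier_probability(
    run_psa(spec, strategies, n = 1200, seed = 14, effect = "detection"))
  for (k in seq_along(labels)) {
    p <- long$p_frontier[k]
    se <- sqrt(max(p * (1 - p), 1e-4) * (1 / 120 + 1 / 1200))
    expect_lt(abs(short$p_frontier[k] - p), 4 * se)
  }
})
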