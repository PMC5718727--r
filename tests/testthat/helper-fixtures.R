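# shared fixtures: all built in code at test time

toy_prevalence <- function() subgroup_prevalence(0.3, 0.2, 0.3, 0.2)

packaged_perf <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(packaged_performance_tables())
    }
    cache
  }
})

# a random row-stochastic perturbation of the packaged tables (structural
# zeros kept), for property tests that should not depend on the packaged
# values alone
random_perf_table <- function(seed, ess = 10) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perf <- packaged_perf()
  probs <- as.matrix(perf[, c("p_nc", "p_noncs", "p_cs")])
  drawn <- t(apply(probs, 1, function(p) {
    pos <- which(p > 0)
    if (length(pos) <= 1L) return(p)
    g <- stats::rgamma(length(pos), shape = p[pos] * ess)
    out <- numeric(length(p))
    out[pos] <- g / sum(g)
    out
  }))
  perf[, c("p_nc", "p_noncs", "p_cs")] <- drawn
  perf
}

# a degenerate table in which every TRUSB always returns NC (zero-sensitivity
# biopsies) while MPMRI and TPMB behave as packaged
blind_biopsy_table <- function() {
  perf <- packaged_perf()
  trusb <- perf$test == "TRUSB"
  perf$p_nc[trusb] <- 1
  perf$p_noncs[trusb] <- 0
  perf$p_cs[trusb] <- 0
  performance_table(as.data.frame(perf))
}

small_bundle <- function(seed = 1) {
  suppressMessages(generate_parameter_set(synthetic_config(seed = seed)))
}

# brute-force frontier oracle: a point is on the frontier iff it is the
# unique net-benefit maximiser at some willingness-to-pay (threshold sweep
# over all pairwise ratios plus extremes)
frontier_oracle_labels <- function(points) {
  n <- nrow(points)
  ratios <- c()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      de <- points$effect[i] - points$effect[j]
      dc <- points$cost[i] - points$cost[j]
      if (de > 0 && dc > 0) ratios <- c(ratios, dc / de)
    }
  }
  ratios <- sort(unique(ratios))
  lambdas <- c(min(ratios, 1) / 2,
               if (length(ratios) > 1)
                 (ratios[-1] + ratios[-length(ratios)]) / 2,
               max(ratios, 1) * 2, 1e-9)
  members <- character(0)
  for (l in lambdas) {
    nb <- l * points$effect - points$cost
    top <- which(nb > max(nb) - 1e-12 * max(1, abs(max(nb))))
    if (length(top) == 1L) members <- c(members, points$label[top])
  }
  sort(unique(members))
}

# z-score of the microsimulated sensitivity against the exact value, on the
# binomial standard error of a proportion among the simulated CS-cancer men
microsim_sensitivity_z <- function(d_exact, m_sim, prev) {
  n_cs <- sum(attr(m_sim, "n_by_subgroup")[cs_subgroups()])
  p <- strategy_sensitivity(d_exact)
  variance <- p * (1 - p) / n_cs
  diff <- strategy_sensitivity(m_sim) - p
  if (variance == 0) {
    if (diff == 0) 0 else Inf
  } else {
    diff / sqrt(variance)
  }
}

random_ce_points <- function(seed, n_points) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  data.frame(
    label = sprintf("S%02d", seq_len(n_points)),
    effect = stats::runif(n_points),
    cost = stats::runif(n_points, 0, 1000)
  )
}
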