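#' Probabilistic sensitivity analysis
#'
#' Parameter uncertainty is propagated by Monte-Carlo simulation: each
#' parameter is given a distribution whose mean equals its point estimate
#' (the standard conjugate conventions for cost-effectiveness analysis:
#' Dirichlet for multinomial classification rows and prevalence, beta for
#' probabilities and utility decrements, gamma for costs), the full pipeline
#' (decision tree plus Markov model) is evaluated per draw, and the
#' probabilistic base case is the per-strategy mean.
#'
#' @name psa
NULL

#' Moment-matched beta parameters
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation, or `NULL` to derive it from a 95% interval
#'   `(lower, upper)` via `sd = (upper - lower) / (2 * 1.96)`.
#' @param lower,upper Optional 95% interval bounds.
#' @return Named vector `c(shape1, shape2)` whose mean is `mean`.
#' @examples
#' beta_moment_match(0.9, lower = 0.86, upper = 0.94)
#' @export
beta_moment_match <- function(mean, sd = NULL, lower = NULL, upper = NULL) {
  stopifnot(mean > 0, mean < 1)
  if (is.null(sd)) {
    stopifnot(!is.null(lower), !is.null(upper), upper > lower)
    sd <- (upper - lower) / (2 * stats::qnorm(0.975))
  }
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("variance too large for a beta distribution with this mean",
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Attach uncertainty distributions to a parameter bundle
#'
#' @param bundle A parameter bundle as returned by
#'   [generate_parameter_set()] (or assembled by hand with the same fields).
#' @param ess Effective sample size for Dirichlet rows (performance tables
#'   and prevalence); concentration = point estimate x `ess`. `Inf` makes the
#'   rows degenerate at the point estimates.
#' @param cost_cv Coefficient of variation for gamma cost distributions
#'   (0 makes costs degenerate).
#' @param probability_ess Effective sample size for beta distributions on
#'   utilities, utility decrements and transition probabilities (`Inf` for
#'   degenerate).
#' @return A list of class `distribution_spec` with the point-estimate bundle
#'   and hyperparameters. All distribution means equal the point estimates.
#' @export
assign_distributions <- function(bundle, ess = 200, cost_cv = 0.2,
                                 probability_ess = 500) {
  if (ess <= 0 || probability_ess <= 0) {
    stop("effective sample sizes must be positive", call. = FALSE)
  }
  stopifnot(cost_cv >= 0)
  validate_prevalence(bundle$prevalence)
  stopifnot(inherits(bundle$performance, "perf_table"))
  structure(
    list(point = bundle, ess = ess, cost_cv = cost_cv,
         probability_ess = probability_ess,
         degenerate = is.infinite(ess) && cost_cv == 0 &&
           is.infinite(probability_ess)),
    class = "distribution_spec"
  )
}

rdirichlet_row <- function(p, ess) {
  out <- numeric(length(p))
  pos <- which(p > 0)
  if (length(pos) <= 1L || is.infinite(ess)) {
    return(p) # structural zeros and degenerate rows are frozen
  }
  g <- stats::rgamma(length(pos), shape = p[pos] * ess)
  if (sum(g) == 0) g <- p[pos]
  out[pos] <- g / sum(g)
  out
}

rbeta_mean <- function(mean, ess) {
  if (is.infinite(ess) || mean <= 0 || mean >= 1) return(mean)
  stats::rbeta(1, mean * ess, (1 - mean) * ess)
}

rgamma_mean <- function(mean, cv) {
  if (cv == 0 || mean == 0) return(mean)
  shape <- 1 / cv^2
  stats::rgamma(1, shape = shape, rate = shape / mean)
}

#' Draw one parameter set from a distribution spec
#'
#' Structural zeros in performance rows are preserved (perfect specificity
#' survives the perturbation) and deterministic rows stay deterministic.
#'
#' @param spec A `distribution_spec`.
#' @return A parameter bundle with the same shape as `spec$point`.
#' @export
draw_parameter_set <- function(spec) {
  stopifnot(inherits(spec, "distribution_spec"))
  bundle <- spec$point
  perf <- bundle$performance
  probs <- as.matrix(perf[, c("p_nc", "p_noncs", "p_cs")])
  drawn <- t(apply(probs, 1, rdirichlet_row, ess = spec$ess))
  perf[, c("p_nc", "p_noncs", "p_cs")] <- drawn
  bundle$performance <- perf

  prev <- rdirichlet_row(as.numeric(bundle$prevalence), spec$ess)
  names(prev) <- names(bundle$prevalence)
  bundle$prevalence <- structure(prev, class = "subgroup_prevalence")

  bundle$unit_costs[] <- vapply(bundle$unit_costs, rgamma_mean,
                                numeric(1), cv = spec$cost_cv)
  for (nm in c("radical_treatment", "surveillance_cycle", "metastatic_cycle")) {
    bundle$costs[[nm]] <- rgamma_mean(bundle$costs[[nm]], spec$cost_cv)
  }
  u <- bundle$utilities
  u$baseline <- rbeta_mean(u$baseline, spec$probability_ess)
  u$metastatic_decrement <- rbeta_mean(u$metastatic_decrement,
                                       spec$probability_ess)
  u$tpmb_decrement <- rbeta_mean(u$tpmb_decrement, spec$probability_ess)
  bundle$utilities <- u

  tr <- bundle$transitions
  for (col in c("p_loc_met", "p_loc_death", "p_met_death")) {
    tr[[col]] <- vapply(tr[[col]], rbeta_mean, numeric(1),
                        ess = spec$probability_ess)
  }
  bundle$transitions <- transition_set(tr)
  bundle
}

#' Evaluate one strategy under one parameter bundle
#'
#' @param strategy A `dx_strategy`.
#' @param bundle A parameter bundle.
#' @param effect `"qaly"` (lifetime QALYs and total costs) or `"detection"`
#'   (CS cancers detected per man and testing cost).
#' @return A list with `effect` and `cost`.
#' @export
evaluate_strategy <- function(strategy, bundle,
                              effect = c("qaly", "detection")) {
  effect <- match.arg(effect)
  d <- execute_strategy(strategy, bundle$performance, bundle$prevalence)
  if (effect == "detection") {
    list(effect = cs_detected_per_man(d),
         cost = expected_testing_cost(d, bundle$unit_costs))
  } else {
    lt <- lifetime_outcomes(
      d, bundle$transitions, bundle$utilities, bundle$costs, bundle$econ,
      background_mortality = bundle$mortality, unit_costs = bundle$unit_costs
    )
    list(effect = lt$total_qalys, cost = lt$total_costs)
  }
}

#' Run a probabilistic sensitivity analysis
#'
#' Draws `n` seeded parameter sets, evaluates every strategy under each, and
#' returns the per-simulation cost and effect arrays. The probabilistic base
#' case is the column mean.
#'
#' @param spec A `distribution_spec` from [assign_distributions()].
#' @param strategies A named list of `dx_strategy` objects (as from
#'   [enumerate_strategies()]) or a single strategy.
#' @param n Number of Monte-Carlo simulations (default 1000).
#' @param seed Integer seed (mandatory).
#' @param effect `"qaly"` or `"detection"` (see [evaluate_strategy()]).
#' @return A list of class `psa_samples`: `cost` and `effect` (`n` x strategy
#'   matrices), `labels`, `n`, `seed`, `effect_type`.
#' @export
run_psa <- function(spec, strategies, n = 1000, seed = 1,
                    effect = c("qaly", "detection")) {
  effect <- match.arg(effect)
  stopifnot(n >= 1)
  if (inherits(strategies, "dx_strategy")) strategies <- list(strategies)
  labels <- vapply(strategies, `[[`, character(1), "label")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  cost <- matrix(NA_real_, nrow = n, ncol = length(strategies),
                 dimnames = list(NULL, labels))
  eff <- cost
  for (s in seq_len(n)) {
    bundle <- draw_parameter_set(spec)
    for (k in seq_along(strategies)) {
      v <- evaluate_strategy(strategies[[k]], bundle, effect = effect)
      cost[s, k] <- v$cost
      eff[s, k] <- v$effect
    }
  }
  structure(
    list(cost = cost, effect = eff, labels = labels, n = n, seed = seed,
         effect_type = effect),
    class = "psa_samples"
  )
}

#' Cost-effectiveness acceptability curves and frontier
#'
#' For each willingness-to-pay threshold, the CEAC of a strategy is the
#' fraction of simulations in which it maximises net monetary benefit (ties
#' broken by label order, so the CEAC values at each threshold sum to 1).
#' The CEAF value at a threshold is the CEAC of the strategy with the highest
#' *expected* net benefit there.
#'
#' @param samples A `psa_samples`.
#' @param thresholds Positive, sorted willingness-to-pay values.
#' @return A data frame: one row per (threshold, strategy) with `ceac`, plus
#'   logical `on_ceaf` marking the strategy carrying the frontier at that
#'   threshold.
#' @export
ceac_ceaf <- function(samples, thresholds) {
  stopifnot(inherits(samples, "psa_samples"), length(thresholds) >= 1,
            all(thresholds > 0), !is.unsorted(thresholds))
  labels <- samples$labels
  ord <- order(labels)
  out <- list()
  for (th in thresholds) {
    nb <- th * samples$effect - samples$cost
    # ties broken by label order: scan columns in label order, strict max
    nb_ordered <- nb[, ord, drop = FALSE]
    winner <- max.col(nb_ordered, ties.method = "first")
    ceac <- tabulate(winner, nbins = length(labels)) / samples$n
    mean_nb <- colMeans(nb_ordered)
    best <- which.max(mean_nb) # first label wins ties
    out[[length(out) + 1L]] <- data.frame(
      threshold = th, label = labels[ord], ceac = ceac,
      on_ceaf = seq_along(labels) == best
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Probability of lying on the efficiency frontier
#'
#' The fraction of simulations in which each strategy is a member of the
#' efficiency frontier computed from that simulation's costs and effects
#' (frontier membership, the default), or in which it maximises net benefit
#' at at least one of the supplied thresholds (`method = "net_benefit"`).
#'
#' Strategies split three ways, mirroring the bubble classification of
#' cost-effectiveness planes: members of the frontier at expected values,
#' strategies with some probability of being on the frontier, and strategies
#' never on it.
#'
#' @param samples A `psa_samples`.
#' @param method `"membership"` or `"net_benefit"`.
#' @param thresholds Thresholds for `method = "net_benefit"`.
#' @return Data frame with `label`, `p_frontier`, `mean_frontier` (membership
#'   of the frontier at the mean costs/effects) and `classification`
#'   (`"frontier"`, `"possible"`, `"never"`).
#' @export
frontier_probability <- function(samples, method = c("membership",
                                                     "net_benefit"),
                                 thresholds = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(samples, "psa_samples"))
  labels <- samples$labels
  counts <- stats::setNames(numeric(length(labels)), labels)
  for (s in seq_len(samples$n)) {
    pts <- data.frame(label = labels, effect = samples$effect[s, ],
                      cost = samples$cost[s, ])
    members <- if (method == "membership") {
      fr <- efficiency_frontier(pts)
      fr$label[fr$on_frontier]
    } else {
      stopifnot(!is.null(thresholds))
      unique(unlist(lapply(thresholds, function(th) {
        nb <- net_benefit(pts, th)
        pts$label[order(-nb, pts$label)][1]
      })))
    }
    counts[members] <- counts[members] + 1
  }
  p <- counts / samples$n
  mean_pts <- data.frame(label = labels,
                         effect = colMeans(samples$effect),
                         cost = colMeans(samples$cost))
  mean_fr <- efficiency_frontier(mean_pts)
  on_mean <- labels %in% mean_fr$label[mean_fr$on_frontier]
  data.frame(
    label = labels,
    p_frontier = unname(p),
    mean_frontier = on_mean,
    classification = ifelse(on_mean, "frontier",
                            ifelse(p > 0, "possible", "never"))
  )
}
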