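#' Synthetic parameter sets
#'
#' The individual-level data behind the long-term parameters (unit costs,
#' utilities, transition probabilities, calibration targets) are not public.
#' This module generates complete, internally consistent, clearly synthetic
#' parameter bundles so the full pipeline is testable: classification tables
#' are Dirichlet perturbations of the packaged performance tables (structural
#' zeros frozen, so perfect specificity survives the noise), costs and
#' utility decrements are drawn within configurable ranges around synthetic
#' defaults of realistic magnitude, and transitions satisfy the
#' treatment-benefit ordering (radical treatment progresses no faster than
#' surveillance). No value here is the published estimate.
#'
#' @name synthetic_data
NULL

#' Synthetic generator configuration
#'
#' @param seed Integer seed (mandatory).
#' @param prevalence A [subgroup_prevalence()]; the default is a synthetic
#'   secondary-care mix, not an estimate from any study.
#' @param perf_ess Effective sample size of the Dirichlet noise applied to
#'   the packaged performance rows; `Inf` reproduces the packaged tables
#'   exactly.
#' @param cost_range,utility_range Half-width, as a fraction of the default
#'   value, of the uniform ranges for costs and utility decrements.
#' @param transition_ranges Data frame of surveillance-management transition
#'   ranges per cancer subgroup: columns `subgroup`, and `lo` / `hi` pairs for
#'   `p_loc_met`, `p_loc_death`, `p_met_death`.
#' @param treatment_benefit_range Range for the multiplier (< 1) applied to
#'   surveillance progression probabilities to obtain the radical-treatment
#'   rows.
#' @param calibration_times Follow-up times (years) at which calibration
#'   targets are generated.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             prevalence = subgroup_prevalence(0.30, 0.20,
                                                              0.30, 0.20),
                             perf_ess = 200,
                             cost_range = 0.25,
                             utility_range = 0.25,
                             transition_ranges = default_transition_ranges(),
                             treatment_benefit_range = c(0.3, 0.7),
                             calibration_times = c(5, 10, 15)) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            perf_ess > 0, cost_range >= 0, cost_range < 1,
            utility_range >= 0, utility_range < 1,
            length(treatment_benefit_range) == 2L,
            all(treatment_benefit_range > 0),
            all(treatment_benefit_range <= 1),
            all(calibration_times > 0))
  validate_prevalence(prevalence)
  structure(
    list(seed = as.integer(seed), prevalence = prevalence,
         perf_ess = perf_ess, cost_range = cost_range,
         utility_range = utility_range,
         transition_ranges = transition_ranges,
         treatment_benefit_range = treatment_benefit_range,
         calibration_times = calibration_times),
    class = "synthetic_config"
  )
}

#' @rdname synthetic_config
#' @export
default_transition_ranges <- function() {
  data.frame(
    subgroup = c("low_risk", "intermediate_risk", "high_risk"),
    p_loc_met_lo = c(0.005, 0.03, 0.06), p_loc_met_hi = c(0.015, 0.05, 0.10),
    p_loc_death_lo = c(0.002, 0.008, 0.015),
    p_loc_death_hi = c(0.008, 0.015, 0.03),
    p_met_death_lo = c(0.12, 0.15, 0.20), p_met_death_hi = c(0.18, 0.22, 0.30)
  )
}

#' Generate a complete synthetic parameter bundle
#'
#' @param cfg A [synthetic_config()].
#' @return A parameter bundle: a list with `performance` (a `perf_table`),
#'   `prevalence`, `unit_costs` (MPMRI/TRUSB/TPMB), `costs` (a
#'   [cost_model()]), `utilities` (a [utility_model()]), `transitions` (a
#'   [transition_set()] for every cancer subgroup under both managements),
#'   `econ` (an [econ_settings()]), `mortality` (a [gompertz_mortality()]
#'   function), `thresholds`, and `calibration_targets` implied by the
#'   generated transitions. Identical seeds give identical bundles.
#' @examples
#' bundle <- generate_parameter_set(synthetic_config(seed = 1))
#' @export
generate_parameter_set <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  perf <- packaged_performance_tables()
  if (!is.infinite(cfg$perf_ess)) {
    probs <- as.matrix(perf[, c("p_nc", "p_noncs", "p_cs")])
    drawn <- t(apply(probs, 1, rdirichlet_row, ess = cfg$perf_ess))
    perf[, c("p_nc", "p_noncs", "p_cs")] <- drawn
  }

  runif_about <- function(centre, range_frac) {
    stats::runif(1, centre * (1 - range_frac), centre * (1 + range_frac))
  }
  unit_costs <- c(
    MPMRI = runif_about(350, cfg$cost_range),
    TRUSB = runif_about(450, cfg$cost_range),
    TPMB = runif_about(1300, cfg$cost_range)
  )
  costs <- cost_model(
    radical_treatment = runif_about(6000, cfg$cost_range),
    surveillance_cycle = runif_about(300, cfg$cost_range),
    metastatic_cycle = runif_about(8000, cfg$cost_range)
  )
  utilities <- utility_model(
    baseline = 0.78, age_slope = 0.003, baseline_age = 65,
    metastatic_decrement = runif_about(0.15, cfg$utility_range),
    tpmb_decrement = runif_about(0.01, cfg$utility_range)
  )

  tr_rows <- list()
  rngs <- cfg$transition_ranges
  for (i in seq_len(nrow(rngs))) {
    sg <- rngs$subgroup[i]
    surv <- c(
      p_loc_met = stats::runif(1, rngs$p_loc_met_lo[i], rngs$p_loc_met_hi[i]),
      p_loc_death = stats::runif(1, rngs$p_loc_death_lo[i],
                                 rngs$p_loc_death_hi[i]),
      p_met_death = stats::runif(1, rngs$p_met_death_lo[i],
                                 rngs$p_met_death_hi[i])
    )
    benefit <- stats::runif(1, cfg$treatment_benefit_range[1],
                            cfg$treatment_benefit_range[2])
    tr_rows[[length(tr_rows) + 1L]] <- data.frame(
      subgroup = sg, management = "surveillance",
      p_loc_met = surv[["p_loc_met"]], p_loc_death = surv[["p_loc_death"]],
      p_met_death = surv[["p_met_death"]]
    )
    tr_rows[[length(tr_rows) + 1L]] <- data.frame(
      subgroup = sg, management = "radical_treatment",
      p_loc_met = surv[["p_loc_met"]] * benefit,
      p_loc_death = surv[["p_loc_death"]] * benefit,
      p_met_death = surv[["p_met_death"]]
    )
  }
  transitions <- transition_set(do.call(rbind, tr_rows))

  schedule <- expand.grid(time = cfg$calibration_times,
                          quantity = c("overall_survival", "metastasis_free"),
                          stringsAsFactors = FALSE)
  targets <- generate_calibration_targets(transitions, schedule,
                                          noise_sd = 0,
                                          seed = cfg$seed + 1L)

  list(
    performance = perf,
    prevalence = cfg$prevalence,
    unit_costs = unit_costs,
    costs = costs,
    utilities = utilities,
    transitions = transitions,
    econ = econ_settings(),
    mortality = gompertz_mortality(),
    thresholds = c(13000, 20000, 30000),
    calibration_targets = targets
  )
}

#' Generate calibration targets from known transitions
#'
#' Computes model-implied target values for every (subgroup, management) cell
#' in `transitions` at the scheduled (time, quantity) pairs, optionally adding
#' truncated Gaussian noise (clamped to \[0, 1\]). With `noise_sd = 0` the
#' targets are exactly model-implied, which makes parameter-recovery
#' experiments possible.
#'
#' @param transitions A [transition_set()].
#' @param schedule Data frame with columns `time` and `quantity`.
#' @param noise_sd Standard deviation of the additive noise (>= 0).
#' @param seed Integer seed.
#' @param cycle_length Cycle length in years.
#' @return A [calibration_targets()] data frame.
#' @export
generate_calibration_targets <- function(transitions, schedule, noise_sd = 0,
                                         seed = 1, cycle_length = 1) {
  stopifnot(noise_sd >= 0)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(transitions))) {
    tr <- as.list(transitions[i, c("p_loc_met", "p_loc_death", "p_met_death")])
    values <- simulate_targets(tr, schedule, cycle_length = cycle_length)
    if (noise_sd > 0) {
      values <- pmin(1, pmax(0, values + stats::rnorm(length(values),
                                                      sd = noise_sd)))
    }
    out[[i]] <- calibration_targets(
      subgroup = transitions$subgroup[i],
      management = transitions$management[i],
      time = schedule$time, quantity = schedule$quantity,
      value = values, weight = 1
    )
  }
  res <- do.call(rbind, out)
  class(res) <- c("calibration_targets", "data.frame")
  res
}
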