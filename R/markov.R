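#' Discount factor
#'
#' Present-value factor `(1 + rate)^(-t)` for an amount accruing `t` years
#' from now.
#'
#' @param t Time in years (>= 0).
#' @param rate Per-annum discount rate as a fraction (>= 0), e.g. `0.035`.
#' @return The discount factor.
#' @examples
#' discount_factor(10, 0.035)
#' @export
discount_factor <- function(t, rate) {
  if (any(t < 0) || any(rate < 0)) {
    stop("time and discount rate must be non-negative", call. = FALSE)
  }
  (1 + rate)^(-t)
}

#' Economic settings
#'
#' @param discount_costs,discount_effects Per-annum discount rates (default
#'   0.035 for both, the UK reference-case rate).
#' @param cycle_length Markov cycle length in years (default 1).
#' @param start_age Cohort age at diagnosis in years (default 65).
#' @param max_age Age at which the model stops (default 100).
#' @param price_year,currency Presentation metadata (defaults 2015, GBP).
#' @return A list of class `econ_settings`.
#' @export
econ_settings <- function(discount_costs = 0.035, discount_effects = 0.035,
                          cycle_length = 1, start_age = 65, max_age = 100,
                          price_year = 2015, currency = "GBP") {
  stopifnot(discount_costs >= 0, discount_effects >= 0, cycle_length > 0,
            start_age >= 0, max_age > start_age)
  structure(
    list(discount_costs = discount_costs, discount_effects = discount_effects,
         cycle_length = cycle_length, start_age = start_age, max_age = max_age,
         price_year = price_year, currency = currency),
    class = "econ_settings"
  )
}

#' Gompertz background mortality schedule
#'
#' Returns a function `(age, cycle_length)` giving the probability of death
#' from other causes within one cycle starting at `age`, from a Gompertz
#' hazard `h(a) = rate * exp(shape * a)`. The defaults give roughly 1% annual
#' other-cause mortality at age 65, rising steeply with age (a synthetic
#' stand-in for a national life table).
#'
#' @param rate,shape Gompertz parameters (> 0).
#' @return A function of `(age, cycle_length)`.
#' @export
gompertz_mortality <- function(rate = 2e-5, shape = 0.095) {
  stopifnot(rate > 0, shape > 0)
  function(age, cycle_length = 1) {
    cum_hazard <- (rate / shape) * (exp(shape * (age + cycle_length)) -
                                      exp(shape * age))
    1 - exp(-cum_hazard)
  }
}

#' Utility model
#'
#' Baseline utility declines linearly with age from `baseline` at
#' `baseline_age`; men in the metastatic state incur `metastatic_decrement`;
#' each TPMB incurs a one-off QALY loss of `tpmb_decrement` (TRUSB has no
#' HRQoL impact). Utilities are clamped to \[0, 1\] after decrements.
#'
#' @param baseline Utility at `baseline_age` (in \[0, 1\]).
#' @param age_slope Utility lost per year of age (>= 0).
#' @param baseline_age Age anchoring the baseline (years).
#' @param metastatic_decrement Per-cycle utility decrement in the metastatic
#'   state (in \[0, 1\]).
#' @param tpmb_decrement One-off QALY loss per TPMB (>= 0).
#' @return A list of class `utility_model`.
#' @export
utility_model <- function(baseline = 0.78, age_slope = 0.003,
                          baseline_age = 65, metastatic_decrement = 0.15,
                          tpmb_decrement = 0.01) {
  stopifnot(baseline >= 0, baseline <= 1, age_slope >= 0,
            metastatic_decrement >= 0, metastatic_decrement <= 1,
            tpmb_decrement >= 0)
  structure(
    list(baseline = baseline, age_slope = age_slope,
         baseline_age = baseline_age,
         metastatic_decrement = metastatic_decrement,
         tpmb_decrement = tpmb_decrement),
    class = "utility_model"
  )
}

utility_at_age <- function(utilities, age) {
  pmin(1, pmax(0, utilities$baseline -
                 utilities$age_slope * (age - utilities$baseline_age)))
}

#' Long-term cost model
#'
#' @param radical_treatment One-off cost of radical prostatectomy including
#'   its complications, applied at diagnosis.
#' @param surveillance_cycle Per-cycle cost of surveillance while in the
#'   localised state under surveillance management.
#' @param metastatic_cycle Per-cycle cost of metastatic disease.
#' @return A list of class `cost_model`. All costs must be non-negative.
#' @export
cost_model <- function(radical_treatment = 6000, surveillance_cycle = 300,
                       metastatic_cycle = 8000) {
  stopifnot(radical_treatment >= 0, surveillance_cycle >= 0,
            metastatic_cycle >= 0)
  structure(
    list(radical_treatment = radical_treatment,
         surveillance_cycle = surveillance_cycle,
         metastatic_cycle = metastatic_cycle),
    class = "cost_model"
  )
}

#' Transition set for the cohort model
#'
#' Per-cycle disease transition probabilities for each (subgroup, management)
#' pair: localised to metastatic, localised to death (disease-specific), and
#' metastatic to death. Background (other-cause) mortality is layered on top
#' by the cohort engine: per cycle, total death probability is
#' `1 - (1 - background)(1 - disease)` and survivors progress with the stated
#' metastasis probability.
#'
#' @param df Data frame with columns `subgroup`, `management`, `p_loc_met`,
#'   `p_loc_death`, `p_met_death`; probabilities in \[0, 1\].
#' @return A data frame of class `transition_set`.
#' @export
transition_set <- function(df) {
  needed <- c("subgroup", "management", "p_loc_met", "p_loc_death",
              "p_met_death")
  stopifnot(is.data.frame(df), all(needed %in% names(df)))
  probs <- as.matrix(df[, c("p_loc_met", "p_loc_death", "p_met_death")])
  if (any(probs < 0 | probs > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(paste(df$subgroup, df$management))) {
    stop("duplicated (subgroup, management) transition rows", call. = FALSE)
  }
  df <- as.data.frame(df)[needed]
  class(df) <- c("transition_set", "data.frame")
  df
}

#' Look up one (subgroup, management) transition row
#'
#' @param transitions A [transition_set()].
#' @param subgroup,management Cell identifiers.
#' @return A list with `p_loc_met`, `p_loc_death`, `p_met_death`; an error if
#'   the cell is absent.
#' @export
transition_row <- function(transitions, subgroup, management) {
  i <- which(transitions$subgroup == subgroup &
               transitions$management == management)
  if (length(i) != 1L) {
    stop("no transition set for subgroup ", subgroup, " under management ",
         management, call. = FALSE)
  }
  as.list(transitions[i, c("p_loc_met", "p_loc_death", "p_met_death")])
}

#' Run the cohort Markov model for one cell
#'
#' Propagates state occupancy cycle by cycle, accruing QALYs and per-cycle
#' costs at the start of each cycle (no half-cycle correction unless
#' `half_cycle = TRUE`) and discounting each cycle's accrual to present value.
#' Men with cancer occupy `localised`, `metastatic`, `dead`; cancer-free men
#' occupy `alive`, `dead`. `dead` is absorbing. One-off costs (radical
#' treatment) and one-off testing decrements are *not* accrued here; see
#' [lifetime_outcomes()].
#'
#' @param transitions For `model = "cancer"`, a list or one-row data frame
#'   with `p_loc_met`, `p_loc_death`, `p_met_death` (per-cycle,
#'   disease-specific). Ignored for `model = "no_cancer"`.
#' @param utilities A [utility_model()].
#' @param costs A [cost_model()].
#' @param econ An [econ_settings()].
#' @param model `"cancer"` (three states) or `"no_cancer"` (two states).
#' @param management `"radical_treatment"`, `"surveillance"` or `"none"`;
#'   surveillance management accrues the per-cycle surveillance cost in the
#'   localised state.
#' @param init Initial occupancy vector (defaults to everyone in `localised`
#'   or `alive`). Must be a probability vector.
#' @param background_mortality A function `(age, cycle_length)` as returned by
#'   [gompertz_mortality()], or `NULL` for no other-cause mortality.
#' @param half_cycle If `TRUE`, accrual uses the mean of start- and
#'   end-of-cycle occupancy.
#' @param survivor_tol Stop once alive occupancy falls below this (and before
#'   `max_age`).
#'
#' @return A list with `qalys`, `costs` (both discounted), `life_years`
#'   (undiscounted), and `trace` (occupancy at the start of each cycle; rows
#'   sum to 1).
#' @examples
#' run_cohort(list(p_loc_met = 0, p_loc_death = 0.1, p_met_death = 0.3),
#'            utility_model(), cost_model(), econ_settings())
#' @export
run_cohort <- function(transitions, utilities, costs, econ,
                       model = c("cancer", "no_cancer"),
                       management = "surveillance",
                       init = NULL,
                       background_mortality = NULL,
                       half_cycle = FALSE,
                       survivor_tol = 1e-12) {
  model <- match.arg(model)
  states <- if (model == "cancer") c("localised", "metastatic", "dead") else
    c("alive", "dead")
  if (is.null(init)) {
    init <- stats::setNames(c(1, rep(0, length(states) - 1L)), states)
  }
  stopifnot(length(init) == length(states), abs(sum(init) - 1) < 1e-9,
            all(init >= 0))
  cl <- econ$cycle_length
  n_cycles <- ceiling((econ$max_age - econ$start_age) / cl)
  occ <- as.numeric(init)
  names(occ) <- states
  trace <- matrix(NA_real_, nrow = n_cycles + 1L, ncol = length(states),
                  dimnames = list(NULL, states))
  qalys <- 0
  cost_total <- 0
  life_years <- 0

  cell_utility <- function(occ, age) {
    u <- utility_at_age(utilities, age)
    if (model == "cancer") {
      um <- max(0, u - utilities$metastatic_decrement)
      occ[["localised"]] * u + occ[["metastatic"]] * um
    } else {
      occ[["alive"]] * u
    }
  }
  cell_cost <- function(occ) {
    if (model == "cancer") {
      surv_cost <- if (identical(management, "surveillance"))
        costs$surveillance_cycle else 0
      occ[["localised"]] * surv_cost +
        occ[["metastatic"]] * costs$metastatic_cycle
    } else {
      0
    }
  }
  step <- function(occ, age) {
    bg <- if (is.null(background_mortality)) 0 else
      background_mortality(age, cl)
    if (model == "cancer") {
      p_d_loc <- 1 - (1 - bg) * (1 - transitions$p_loc_death)
      p_d_met <- 1 - (1 - bg) * (1 - transitions$p_met_death)
      p_met <- (1 - p_d_loc) * transitions$p_loc_met
      new_loc <- occ[["localised"]] * (1 - p_d_loc - p_met)
      new_met <- occ[["localised"]] * p_met +
        occ[["metastatic"]] * (1 - p_d_met)
      new_dead <- occ[["dead"]] + occ[["localised"]] * p_d_loc +
        occ[["metastatic"]] * p_d_met
      c(localised = new_loc, metastatic = new_met, dead = new_dead)
    } else {
      c(alive = occ[["alive"]] * (1 - bg),
        dead = occ[["dead"]] + occ[["alive"]] * bg)
    }
  }

  for (t in seq_len(n_cycles + 1L) - 1L) {
    trace[t + 1L, ] <- occ
    age <- econ$start_age + t * cl
    alive <- 1 - occ[["dead"]]
    if (t == n_cycles || alive < survivor_tol) {
      trace <- trace[seq_len(t + 1L), , drop = FALSE]
      break
    }
    occ_accrual <- occ
    if (half_cycle) {
      occ_next <- step(occ, age)
      occ_accrual <- (occ + occ_next) / 2
    }
    years <- t * cl
    df_e <- discount_factor(years, econ$discount_effects)
    df_c <- discount_factor(years, econ$discount_costs)
    qalys <- qalys + cl * df_e * cell_utility(occ_accrual, age)
    life_years <- life_years + cl * (1 - occ_accrual[["dead"]])
    cost_total <- cost_total + df_c * cell_cost(occ_accrual)
    occ <- step(occ, age)
  }
  list(qalys = unname(qalys), costs = unname(cost_total),
       life_years = unname(life_years), trace = trace)
}
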