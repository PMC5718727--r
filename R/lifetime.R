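#' Management implied by a diagnosis
#'
#' A CS-cancer diagnosis leads to immediate radical treatment; men with
#' cancer in whom CS cancer was not diagnosed (correctly diagnosed non-CS
#' cancer, or missed cancer) are managed by surveillance; cancer-free men
#' without a CS diagnosis receive no management.
#'
#' @param subgroup True disease subgroup.
#' @param diagnosis Final diagnosis (`no_cancer_dx`, `nonCS_dx`, `CS_dx`).
#' @return One of `"radical_treatment"`, `"surveillance"`, `"none"`.
#' @export
management_for <- function(subgroup, diagnosis) {
  if (diagnosis == "CS_dx") {
    "radical_treatment"
  } else if (subgroup != "no_cancer") {
    "surveillance"
  } else {
    "none"
  }
}

#' Discounted lifetime outcomes of a diagnosis distribution
#'
#' Attaches the cohort Markov model to every (subgroup, diagnosis) cell of a
#' diagnosis distribution: each cell's management follows [management_for()],
#' its discounted QALYs and long-term costs come from [run_cohort()], the
#' one-off radical-treatment cost is added to cells managed by radical
#' treatment, the one-off TPMB QALY decrement is subtracted per expected
#' TPMB, and the testing cost from [expected_testing_cost()] is added when
#' `unit_costs` is supplied. Strategy totals are prevalence- and
#' probability-weighted sums.
#'
#' @param d A `dx_distribution`.
#' @param transitions A [transition_set()] covering every reachable
#'   (subgroup, management) pair with cancer.
#' @param utilities A [utility_model()].
#' @param costs A [cost_model()].
#' @param econ An [econ_settings()].
#' @param background_mortality Function from [gompertz_mortality()] or `NULL`.
#' @param unit_costs Optional named vector (`MPMRI`, `TRUSB`, `TPMB`); when
#'   supplied, the expected testing cost is included in the total cost.
#' @param half_cycle Passed to [run_cohort()].
#'
#' @return A list of class `lifetime_result`: `cells` (per subgroup x
#'   diagnosis: probability, management, discounted QALYs and long-term
#'   costs per man in the cell), `total_qalys`, `total_costs`,
#'   `testing_cost`.
#' @export
lifetime_outcomes <- function(d, transitions, utilities, costs, econ,
                              background_mortality = NULL,
                              unit_costs = NULL, half_cycle = FALSE) {
  stopifnot(inherits(d, "dx_distribution"))
  prev <- attr(d, "prevalence")
  cells <- unique(d[, c("subgroup", "diagnosis")])
  cells$prob <- mapply(function(sg, dx) dx_prob(d, sg, dx),
                       cells$subgroup, cells$diagnosis)
  cells$management <- mapply(management_for, cells$subgroup, cells$diagnosis)

  cache <- new.env(parent = emptyenv())
  cell_value <- function(subgroup, management) {
    key <- paste(subgroup, management)
    if (!is.null(cache[[key]])) return(cache[[key]])
    value <- if (subgroup == "no_cancer") {
      run_cohort(NULL, utilities, costs, econ, model = "no_cancer",
                 management = management,
                 background_mortality = background_mortality,
                 half_cycle = half_cycle)
    } else {
      run_cohort(transition_row(transitions, subgroup, management),
                 utilities, costs, econ, model = "cancer",
                 management = management,
                 background_mortality = background_mortality,
                 half_cycle = half_cycle)
    }
    cache[[key]] <- value
    value
  }

  cells$qalys <- NA_real_
  cells$longterm_cost <- NA_real_
  for (i in seq_len(nrow(cells))) {
    v <- cell_value(cells$subgroup[i], cells$management[i])
    one_off <- if (cells$management[i] == "radical_treatment")
      costs$radical_treatment else 0
    cells$qalys[i] <- v$qalys
    cells$longterm_cost[i] <- v$costs + one_off
  }

  weight <- prev[cells$subgroup] * cells$prob
  tpmb_loss <- utilities$tpmb_decrement * expected_tpmb_count(d)
  testing_cost <- if (is.null(unit_costs)) 0 else
    expected_testing_cost(d, unit_costs)
  structure(
    list(
      cells = cells,
      total_qalys = sum(weight * cells$qalys) - tpmb_loss,
      total_costs = sum(weight * cells$longterm_cost) + testing_cost,
      testing_cost = testing_cost
    ),
    class = "lifetime_result"
  )
}
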