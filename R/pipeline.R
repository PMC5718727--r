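#' Deterministic base-case analysis
#'
#' Evaluates every selected strategy at the bundle's point estimates:
#' decision-tree accuracy margins, expected testing cost, lifetime QALYs and
#' costs, then the detection-per-pound and cost-per-QALY efficiency
#' frontiers.
#'
#' @param bundle A parameter bundle (see [generate_parameter_set()]).
#' @param strategies A named list of `dx_strategy` objects, a character
#'   vector of labels to parse, or `NULL` for the full enumerated grid.
#' @param out_dir Optional directory; when given, the results table is
#'   written to `base_case.csv` there.
#' @return A data frame of class `base_case` with one row per strategy:
#'   `label`, `sensitivity`, `specificity`, `detected`, `testing_cost`,
#'   `qalys`, `lifetime_cost`, frontier membership flags and ICERs on both
#'   planes.
#' @examples
#' bundle <- generate_parameter_set(synthetic_config(seed = 1))
#' run_base_case(bundle, strategies = c("M7 222", "P4 2", "T1 2"))
#' @export
run_base_case <- function(bundle, strategies = NULL, out_dir = NULL) {
  strategies <- resolve_strategies(strategies)
  rows <- lapply(strategies, function(strategy) {
    d <- execute_strategy(strategy, bundle$performance, bundle$prevalence)
    lt <- lifetime_outcomes(
      d, bundle$transitions, bundle$utilities, bundle$costs, bundle$econ,
      background_mortality = bundle$mortality, unit_costs = bundle$unit_costs
    )
    data.frame(
      label = strategy$label,
      sensitivity = strategy_sensitivity(d),
      specificity = strategy_specificity(d),
      detected = cs_detected_per_man(d),
      testing_cost = lt$testing_cost,
      qalys = lt$total_qalys,
      lifetime_cost = lt$total_costs
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  det <- detection_frontier(res)
  det <- det[match(res$label, det$label), ]
  res$detection_frontier <- det$on_frontier
  res$detection_icer <- det$icer

  qal <- efficiency_frontier(data.frame(label = res$label,
                                        effect = res$qalys,
                                        cost = res$lifetime_cost))
  qal <- qal[match(res$label, qal$label), ]
  res$qaly_frontier <- qal$on_frontier
  res$qaly_icer <- qal$icer

  class(res) <- c("base_case", "data.frame")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res, file.path(out_dir, "base_case.csv"),
                     row.names = FALSE)
  }
  res
}

resolve_strategies <- function(strategies) {
  if (is.null(strategies)) {
    return(enumerate_strategies(warn_grid_size = FALSE))
  }
  if (inherits(strategies, "dx_strategy")) {
    strategies <- list(strategies)
  }
  if (is.character(strategies)) {
    strategies <- lapply(strategies, parse_strategy_label)
  }
  stopifnot(all(vapply(strategies, inherits, logical(1), "dx_strategy")))
  names(strategies) <- vapply(strategies, `[[`, character(1), "label")
  strategies
}

#' Scenario (sensitivity) analysis
#'
#' Re-runs the deterministic base case under modified parameters and reports
#' the comparison: which strategies changed frontier membership, and the
#' cost-effective strategy (maximum net benefit on the QALY plane) at each
#' threshold before and after.
#'
#' Overrides address bundle entries by dotted paths, e.g.
#' `list("unit_costs.MPMRI" = 500)` or
#' `list("utilities.metastatic_decrement" = 0.2)`. Overriding a path that
#' does not exist in the bundle is an error.
#'
#' @param bundle A parameter bundle.
#' @param overrides Named list of dotted-path overrides (may be empty).
#' @param strategies As in [run_base_case()].
#' @return A list of class `scenario_result`: `base`, `scenario` (both
#'   `base_case` tables), `overrides`, `frontier_changes` (labels whose QALY-
#'   or detection-frontier membership changed) and `cost_effective` (per
#'   threshold, the net-benefit-maximising label before and after).
#' @export
run_scenario <- function(bundle, overrides = list(), strategies = NULL) {
  strategies <- resolve_strategies(strategies)
  base <- run_base_case(bundle, strategies)
  modified <- apply_overrides(bundle, overrides)
  scenario <- run_base_case(modified, strategies)

  changed <- base$label[
    base$qaly_frontier != scenario$qaly_frontier |
      base$detection_frontier != scenario$detection_frontier
  ]
  ce <- do.call(rbind, lapply(bundle$thresholds, function(th) {
    pick <- function(res) {
      nb <- th * res$qalys - res$lifetime_cost
      res$label[order(-nb, res$label)][1]
    }
    data.frame(threshold = th, base = pick(base), scenario = pick(scenario))
  }))
  structure(
    list(base = base, scenario = scenario, overrides = overrides,
         frontier_changes = changed, cost_effective = ce),
    class = "scenario_result"
  )
}

apply_overrides <- function(bundle, overrides) {
  if (!length(overrides)) return(bundle)
  stopifnot(is.list(overrides), !is.null(names(overrides)),
            all(nzchar(names(overrides))))
  for (path in names(overrides)) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    node <- bundle
    for (k in seq_along(parts)) {
      nm <- parts[k]
      if (is.null(names(node)) || !nm %in% names(node)) {
        stop("override path ", sQuote(path), " names no bundle parameter",
             call. = FALSE)
      }
      node <- node[[nm]]
    }
    bundle <- assign_path(bundle, parts, overrides[[path]])
  }
  bundle
}

assign_path <- function(node, parts, value) {
  if (length(parts) == 1L) {
    node[[parts]] <- value
    return(node)
  }
  node[[parts[1]]] <- assign_path(node[[parts[1]]], parts[-1], value)
  node
}
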