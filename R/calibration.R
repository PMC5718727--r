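#' Calibration of transition probabilities to survival targets
#'
#' The per-cycle transition probabilities of the cohort model are rarely
#' observed directly; instead, trial reports state overall survival and
#' metastasis-free fractions at given follow-up times. These functions fit
#' the three free transition probabilities of a (subgroup, management) cell
#' so the model reproduces such targets, by bounded weighted least squares
#' with seeded multi-start.
#'
#' Targets are *disease-specific*: the forward map runs the three-state model
#' without background mortality, so target values should be net of
#' other-cause mortality (as trial survival curves versus matched controls
#' typically are).
#'
#' @name calibration
NULL

#' Build a calibration target table
#'
#' @param subgroup,management Cell identifiers.
#' @param time Follow-up times in years (> 0).
#' @param quantity `"overall_survival"` (1 - dead occupancy) or
#'   `"metastasis_free"` (localised occupancy).
#' @param value Target values in \[0, 1\].
#' @param weight Positive weights (default 1).
#' @return A data frame of class `calibration_targets`.
#' @export
calibration_targets <- function(subgroup, management, time, quantity, value,
                                weight = 1) {
  df <- data.frame(subgroup = subgroup, management = management, time = time,
                   quantity = quantity, value = value, weight = weight)
  stopifnot(all(df$time > 0), all(df$value >= 0 & df$value <= 1),
            all(df$weight > 0),
            all(df$quantity %in% c("overall_survival", "metastasis_free")))
  class(df) <- c("calibration_targets", "data.frame")
  df
}

#' Model-implied values of calibration quantities
#'
#' Runs the three-state disease model (no background mortality) from an
#' all-localised cohort and reads the requested quantities at the requested
#' times, interpolating linearly between cycle boundaries when a time is not
#' a multiple of the cycle length.
#'
#' @param transitions A list with `p_loc_met`, `p_loc_death`, `p_met_death`.
#' @param schedule Data frame with columns `time` (years) and `quantity`.
#' @param cycle_length Cycle length in years (default 1).
#' @return Numeric vector of model-implied values, one per schedule row.
#' @examples
#' simulate_targets(list(p_loc_met = 0, p_loc_death = 0.1, p_met_death = 0),
#'                  data.frame(time = 5, quantity = "overall_survival"))
#' @export
simulate_targets <- function(transitions, schedule, cycle_length = 1) {
  stopifnot(all(c("time", "quantity") %in% names(schedule)))
  horizon <- max(schedule$time) + 2 * cycle_length
  econ <- econ_settings(cycle_length = cycle_length, start_age = 0,
                        max_age = horizon)
  fit <- run_cohort(transitions, utility_model(), cost_model(), econ,
                    model = "cancer", survivor_tol = 0)
  trace <- fit$trace
  cycle_times <- (seq_len(nrow(trace)) - 1L) * cycle_length
  read_at <- function(time, quantity) {
    series <- switch(quantity,
      overall_survival = 1 - trace[, "dead"],
      metastasis_free = trace[, "localised"],
      stop("unknown calibration quantity ", sQuote(quantity), call. = FALSE)
    )
    stats::approx(cycle_times, series, xout = time, rule = 2)$y
  }
  mapply(read_at, schedule$time, schedule$quantity)
}

#' Calibrate transition probabilities to targets
#'
#' Minimises the weighted squared error between model-implied and stated
#' target values over the three per-cycle transition probabilities of each
#' (subgroup, management) cell appearing in `targets`, using bounded
#' L-BFGS-B with seeded multi-start. An identifiability diagnostic counts
#' targets against the three free parameters per cell.
#'
#' @param targets A [calibration_targets()] data frame.
#' @param lower,upper Bounds on each transition probability (within \[0, 1\]).
#' @param init Optional named list mapping `"subgroup management"` to a
#'   3-vector `(p_loc_met, p_loc_death, p_met_death)` used as the first
#'   start; remaining starts are seeded uniform draws within the bounds.
#' @param n_starts Number of optimisation starts per cell (default 10).
#' @param seed Integer seed for the multi-start draws.
#' @param cycle_length Cycle length in years.
#' @param tol Convergence tolerance on the objective (default 1e-8).
#'
#' @return A list of class `calibration_result`: `transitions` (a
#'   [transition_set()]), `objective` (summed best objectives), `converged`,
#'   and `diagnostics` (per-cell target counts, objective values, and an
#'   `underdetermined` flag when a cell has fewer targets than parameters).
#' @export
calibrate_transitions <- function(targets, lower = 0, upper = 0.9,
                                  init = NULL, n_starts = 10, seed = 1,
                                  cycle_length = 1, tol = 1e-8) {
  stopifnot(nrow(targets) >= 1, lower >= 0, upper <= 1, lower < upper,
            n_starts >= 1)
  if (all(targets$weight == 0)) {
    stop("all calibration weights are zero", call. = FALSE)
  }
  cells <- unique(targets[, c("subgroup", "management")])
  par_names <- c("p_loc_met", "p_loc_death", "p_met_death")

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  rows <- list()
  diagnostics <- list()
  total_obj <- 0
  converged <- TRUE
  for (i in seq_len(nrow(cells))) {
    sg <- cells$subgroup[i]
    mg <- cells$management[i]
    cell_targets <- targets[targets$subgroup == sg & targets$management == mg,
                            , drop = FALSE]
    objective <- function(par) {
      tr <- as.list(stats::setNames(par, par_names))
      sim <- simulate_targets(tr, cell_targets, cycle_length = cycle_length)
      sum(cell_targets$weight * (sim - cell_targets$value)^2)
    }
    starts <- matrix(stats::runif(3 * n_starts, lower, upper),
                     ncol = 3, dimnames = list(NULL, par_names))
    key <- paste(sg, mg)
    if (!is.null(init) && !is.null(init[[key]])) {
      starts[1, ] <- init[[key]]
    }
    best <- NULL
    for (s in seq_len(n_starts)) {
      fit <- stats::optim(starts[s, ], objective, method = "L-BFGS-B",
                          lower = rep(lower, 3), upper = rep(upper, 3),
                          control = list(factr = 1e3, maxit = 500))
      if (is.null(best) || fit$value < best$value) best <- fit
      if (best$value < tol) break
    }
    rows[[i]] <- data.frame(subgroup = sg, management = mg,
                            p_loc_met = best$par[["p_loc_met"]],
                            p_loc_death = best$par[["p_loc_death"]],
                            p_met_death = best$par[["p_met_death"]])
    n_cell_targets <- nrow(cell_targets)
    diagnostics[[i]] <- data.frame(
      subgroup = sg, management = mg, n_targets = n_cell_targets,
      n_parameters = 3L, underdetermined = n_cell_targets < 3L,
      objective = best$value, converged = best$convergence == 0
    )
    total_obj <- total_obj + best$value
    converged <- converged && best$convergence == 0
  }
  structure(
    list(
      transitions = transition_set(do.call(rbind, rows)),
      objective = total_obj,
      converged = converged,
      diagnostics = do.call(rbind, diagnostics)
    ),
    class = "calibration_result"
  )
}
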