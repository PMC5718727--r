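#' Exact evaluation of a diagnostic strategy
#'
#' Propagates each disease subgroup through the strategy's stages, multiplying
#' subgroup-conditional classification probabilities along every branch.
#' Results of successive tests are conditionally independent given the true
#' subgroup and the test context; history dependence of repeat biopsies is
#' carried entirely by the TRUSB type of the context. The final diagnosis is
#' the most severe *biopsy* result observed on the path (CS > nonCS > NC);
#' imaging suspicion alone never yields a cancer diagnosis, and a man with no
#' biopsy exits with a no-cancer diagnosis.
#'
#' @param strategy A `dx_strategy` from [parse_strategy_label()] or
#'   [enumerate_strategies()].
#' @param perf A `perf_table` covering every test context the strategy can
#'   reach.
#' @param prevalence A [subgroup_prevalence()] vector.
#'
#' @return An object of class `dx_distribution`: a data frame of cells
#'   `(subgroup, diagnosis, n_mpmri, n_trusb, n_tpmb, prob)` where `prob` is
#'   the probability of the cell conditional on the subgroup, with the
#'   prevalence attached as an attribute. Within each subgroup the cell
#'   probabilities sum to 1.
#' @examples
#' perf <- packaged_performance_tables()
#' prev <- subgroup_prevalence(0.3, 0.2, 0.3, 0.2)
#' d <- execute_strategy(parse_strategy_label("M7 222"), perf, prev)
#' strategy_sensitivity(d)
#' @export
execute_strategy <- function(strategy, perf, prevalence) {
  stopifnot(inherits(strategy, "dx_strategy"), inherits(perf, "perf_table"))
  validate_prevalence(prevalence)
  lookup <- perf_lookup(perf)
  stages <- strategy$stages
  n_stages <- length(stages)
  classes <- test_class_levels()
  cells <- list()

  record <- function(subgroup, results, p) {
    executed <- !is.na(results)
    tests <- vapply(stages[executed], `[[`, character(1), "test")
    biopsy <- tests %in% c("TRUSB", "TPMB")
    sev <- class_severity(results[executed][biopsy])
    dx <- if (length(sev)) severity_to_diagnosis(max(sev)) else "no_cancer_dx"
    cells[[length(cells) + 1L]] <<- data.frame(
      subgroup = subgroup, diagnosis = dx,
      n_mpmri = sum(tests == "MPMRI"),
      n_trusb = sum(tests == "TRUSB"),
      n_tpmb = sum(tests == "TPMB"),
      prob = p
    )
  }

  walk <- function(subgroup, i, results, p) {
    if (p == 0) return(invisible())
    if (i > n_stages) {
      record(subgroup, results, p)
      return(invisible())
    }
    stage <- stages[[i]]
    if (!stage_applies(stage, results, stages)) {
      walk(subgroup, i + 1L, results, p)
      return(invisible())
    }
    probs <- perf_row(lookup, stage$context, subgroup)
    for (k in seq_along(classes)) {
      if (probs[k] > 0) {
        r <- results
        r[i] <- classes[k]
        walk(subgroup, i + 1L, r, p * probs[k])
      }
    }
  }

  for (subgroup in subgroup_levels()) {
    walk(subgroup, 1L, rep(NA_character_, n_stages), 1)
  }
  cells <- do.call(rbind, cells)
  cells <- stats::aggregate(
    prob ~ subgroup + diagnosis + n_mpmri + n_trusb + n_tpmb,
    data = cells, FUN = sum
  )
  totals <- tapply(cells$prob, cells$subgroup, sum)
  stopifnot(all(abs(totals - 1) < 1e-9))
  structure(
    cells[order(cells$subgroup, cells$diagnosis), , drop = FALSE],
    prevalence = prevalence,
    label = strategy$label,
    class = c("dx_distribution", "data.frame")
  )
}

#' @export
print.dx_distribution <- function(x, ...) {
  cat("<dx_distribution> strategy ", attr(x, "label"), "\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

dx_prob <- function(d, subgroup, diagnosis) {
  sum(d$prob[d$subgroup == subgroup & d$diagnosis == diagnosis])
}

#' Sensitivity of a strategy for clinically significant cancer
#'
#' The probability of a CS-cancer diagnosis among men whose true subgroup is
#' intermediate- or high-risk, weighting the two CS subgroups by prevalence.
#'
#' @param d A `dx_distribution`.
#' @return A probability.
#' @export
strategy_sensitivity <- function(d) {
  prev <- attr(d, "prevalence")
  cs <- cs_subgroups()
  denom <- sum(prev[cs])
  if (denom <= 0) {
    stop("sensitivity is undefined when CS prevalence is zero", call. = FALSE)
  }
  # computed through the complement: strategies whose undetected men all
  # terminate in the reference-standard biopsy have no non-CS cells at all,
  # so their sensitivity is exactly 1 (no floating-point residue from
  # summing path products)
  num <- sum(vapply(cs, function(sg) {
    prev[[sg]] * (1 - dx_prob(d, sg, "nonCS_dx") -
                    dx_prob(d, sg, "no_cancer_dx"))
  }, numeric(1)))
  num / denom
}

#' Specificity of a strategy for clinically significant cancer
#'
#' The probability of *not* receiving a CS-cancer diagnosis among men whose
#' true subgroup is cancer-free or low-risk, weighted by prevalence.
#'
#' @param d A `dx_distribution`.
#' @return A probability.
#' @export
strategy_specificity <- function(d) {
  prev <- attr(d, "prevalence")
  non_cs <- c("no_cancer", "low_risk")
  denom <- sum(prev[non_cs])
  if (denom <= 0) {
    stop("specificity is undefined when non-CS prevalence is zero",
         call. = FALSE)
  }
  num <- sum(vapply(non_cs, function(sg) {
    prev[[sg]] * (1 - dx_prob(d, sg, "CS_dx"))
  }, numeric(1)))
  num / denom
}

#' Clinically significant cancers detected per man referred
#'
#' The joint probability of having CS cancer and receiving a CS diagnosis,
#' i.e. prevalence-weighted true positives per man entering the pathway.
#'
#' @param d A `dx_distribution`.
#' @return A probability (cancers detected per man).
#' @export
cs_detected_per_man <- function(d) {
  prev <- attr(d, "prevalence")
  sum(vapply(cs_subgroups(), function(sg) {
    prev[[sg]] * dx_prob(d, sg, "CS_dx")
  }, numeric(1)))
}

#' Per-subgroup referral probabilities and expected test counts
#'
#' @param d A `dx_distribution`.
#' @return A data frame with one row per subgroup: `p_biopsy` (probability of
#'   receiving at least one biopsy of any kind), and expected counts
#'   `e_mpmri`, `e_trusb`, `e_tpmb` of each test.
#' @export
referral_rates <- function(d) {
  out <- do.call(rbind, lapply(subgroup_levels(), function(sg) {
    rows <- d[d$subgroup == sg, , drop = FALSE]
    data.frame(
      subgroup = sg,
      p_biopsy = sum(rows$prob[rows$n_trusb + rows$n_tpmb >= 1]),
      e_mpmri = sum(rows$prob * rows$n_mpmri),
      e_trusb = sum(rows$prob * rows$n_trusb),
      e_tpmb = sum(rows$prob * rows$n_tpmb)
    )
  }))
  rownames(out) <- out$subgroup
  out
}

#' Expected testing cost per man referred
#'
#' Prevalence-weighted expected sum of the unit costs of the tests
#' administered. Unit costs should include the expected cost of managing
#' test-related complications.
#'
#' @param d A `dx_distribution`.
#' @param unit_costs Named numeric vector with elements `MPMRI`, `TRUSB`,
#'   `TPMB` (money per test, non-negative).
#' @return Money per man.
#' @export
expected_testing_cost <- function(d, unit_costs) {
  stopifnot(all(test_kinds() %in% names(unit_costs)))
  if (any(unit_costs < 0)) {
    stop("unit costs must be non-negative", call. = FALSE)
  }
  prev <- attr(d, "prevalence")
  rates <- referral_rates(d)
  per_subgroup <- rates$e_mpmri * unit_costs[["MPMRI"]] +
    rates$e_trusb * unit_costs[["TRUSB"]] +
    rates$e_tpmb * unit_costs[["TPMB"]]
  sum(prev[rates$subgroup] * per_subgroup)
}

#' Expected number of TPMBs per man referred
#'
#' Used for the one-off health-related quality-of-life decrement of TPMB.
#'
#' @param d A `dx_distribution`.
#' @return Expected TPMB count per man.
#' @export
expected_tpmb_count <- function(d) {
  prev <- attr(d, "prevalence")
  rates <- referral_rates(d)
  sum(prev[rates$subgroup] * rates$e_tpmb)
}

#' Microsimulation oracle for the decision-tree engine
#'
#' Simulates `n` individual men through the strategy's routing rules and
#' returns the empirical diagnosis distribution in the same format as
#' [execute_strategy()]. Used to validate the exact propagation engine.
#'
#' @param strategy A `dx_strategy`.
#' @param perf A `perf_table`.
#' @param prevalence A [subgroup_prevalence()] vector.
#' @param n Number of simulated men (>= 1).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return A `dx_distribution` with empirical cell probabilities (conditional
#'   on subgroup) and attributes `n` and `n_by_subgroup`.
#' @export
microsim_oracle <- function(strategy, perf, prevalence, n, seed) {
  stopifnot(inherits(strategy, "dx_strategy"), n >= 1)
  validate_prevalence(prevalence)
  lookup <- perf_lookup(perf)
  stages <- strategy$stages
  n_stages <- length(stages)
  classes <- test_class_levels()

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  subgroup <- sample(subgroup_levels(), n, replace = TRUE, prob = prevalence)
  results <- matrix(NA_character_, nrow = n, ncol = max(n_stages, 1L))
  is_biopsy <- vapply(stages, function(s) s$test %in% c("TRUSB", "TPMB"),
                      logical(1))

  for (i in seq_len(n_stages)) {
    stage <- stages[[i]]
    applies <- rep(TRUE, n)
    for (r in stage$requires) {
      applies <- applies & !is.na(results[, r$stage]) &
        results[, r$stage] %in% r$result_in
    }
    if (isTRUE(stage$requires_no_cs)) {
      prior_biopsy <- which(is_biopsy[seq_len(i - 1L)])
      if (length(prior_biopsy)) {
        any_cs <- rowSums(
          results[, prior_biopsy, drop = FALSE] == "CS", na.rm = TRUE
        ) > 0
        applies <- applies & !any_cs
      }
    }
    for (sg in subgroup_levels()) {
      idx <- which(applies & subgroup == sg)
      if (!length(idx)) next
      probs <- perf_row(lookup, stage$context, sg)
      results[idx, i] <- sample(classes, length(idx), replace = TRUE,
                                prob = probs)
    }
  }

  executed <- !is.na(results)
  tests <- vapply(stages, `[[`, character(1), "test")
  n_mpmri <- rowSums(executed[, tests == "MPMRI", drop = FALSE])
  n_trusb <- rowSums(executed[, tests == "TRUSB", drop = FALSE])
  n_tpmb <- rowSums(executed[, tests == "TPMB", drop = FALSE])
  biopsy_cs <- rowSums(
    results[, is_biopsy, drop = FALSE] == "CS", na.rm = TRUE) > 0
  biopsy_noncs <- rowSums(
    results[, is_biopsy, drop = FALSE] == "nonCS", na.rm = TRUE) > 0
  dx <- ifelse(biopsy_cs, "CS_dx",
               ifelse(biopsy_noncs, "nonCS_dx", "no_cancer_dx"))

  df <- data.frame(subgroup = subgroup, diagnosis = dx, n_mpmri = n_mpmri,
                   n_trusb = n_trusb, n_tpmb = n_tpmb)
  counts <- stats::aggregate(
    cbind(count = rep(1L, nrow(df))) ~ subgroup + diagnosis + n_mpmri +
      n_trusb + n_tpmb, data = df, FUN = sum
  )
  sg_n <- table(factor(subgroup, levels = subgroup_levels()))
  counts$prob <- counts$count / as.numeric(sg_n[counts$subgroup])
  counts$count <- NULL
  structure(
    counts[order(counts$subgroup, counts$diagnosis), , drop = FALSE],
    prevalence = prevalence,
    label = strategy$label,
    n = n,
    n_by_subgroup = sg_n,
    class = c("dx_distribution", "data.frame")
  )
}
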