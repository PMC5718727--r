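#' Diagnostic strategies
#'
#' A strategy is a labelled, history-dependent sequence of up to three tests.
#' Labels follow the grammar `"<combination> <digits>"`: the combination code
#' (M1-M7, N1-N7, T1-T9, P1-P9) followed by the biopsy histology definition
#' (1 or 2) and, when the combination uses MPMRI, the imaging definition
#' (1 or 2) and suspicion cut-off (2-5). For example `"M1 125"` is combination
#' M1 with histology definition 1, MPMRI definition 2 and cut-off 5; `"P4 2"`
#' is combination P4 with histology definition 2 and no MPMRI.
#'
#' Combination families:
#' * **M**: MPMRI first, then MRI-targeted TRUSB in men whose scan meets the
#'   referral rule (CS suspicion for M1/M3/M5/M7, any suspicion for M2/M4/M6),
#'   then (M3-M7) a repeat MRI-targeted TRUSB when the first biopsy result
#'   triggers it (M3/M4: non-CS found; M5/M6: nothing found; M7: CS not
#'   found) and the scan was suspicious of CS cancer.
#' * **N**: as M for the scan and first biopsy, but every man in whom CS
#'   cancer has not been detected terminates in a TPMB.
#' * **T**: TRUSB first. T2/T3/T4 repeat the TRUSB when the first found
#'   nothing / non-CS cancer / either. T5-T9 offer MPMRI to men whose first
#'   biopsy found nothing (T5, T8), non-CS cancer (T6) or either (T7, T9),
#'   with an MRI-targeted repeat TRUSB when the scan shows CS suspicion
#'   (T5-T7) or any suspicion (T8, T9).
#' * **P**: as T, but undetected men terminate in a TPMB (P1 is TPMB alone).
#'
#' A diagnosis of CS cancer always requires a biopsy: imaging suspicion alone
#' never yields a cancer diagnosis.
#'
#' @name strategy
NULL

ANY_SUSPICION <- c("nonCS", "CS")
CS_SUSPICION <- "CS"
NOT_CS <- c("NC", "nonCS")

combination_codes <- function() {
  c(paste0("M", 1:7), paste0("N", 1:7), paste0("T", 1:9), paste0("P", 1:9))
}

combination_uses_mpmri <- function(combination) {
  family <- substr(combination, 1, 1)
  index <- as.integer(substr(combination, 2, 2))
  family %in% c("M", "N") | (family %in% c("T", "P") & index >= 5)
}

# --- stage helpers ----------------------------------------------------------

new_stage <- function(test, trusb_type = NA_integer_, requires = list(),
                      requires_no_cs = FALSE) {
  list(test = test, trusb_type = trusb_type, requires = requires,
       requires_no_cs = requires_no_cs)
}

req <- function(stage, result_in) list(stage = stage, result_in = result_in)

m_refer_set <- function(index) {
  if (index %in% c(1L, 3L, 5L, 7L)) CS_SUSPICION else ANY_SUSPICION
}

m_rebiopsy_trigger <- function(index) {
  switch(as.character(index),
    "3" = , "4" = "nonCS",
    "5" = , "6" = "NC",
    "7" = NOT_CS,
    NULL
  )
}

t_mri_set <- function(index) {
  switch(as.character(index),
    "2" = , "5" = , "8" = "NC",
    "3" = , "6" = "nonCS",
    "4" = , "7" = , "9" = NOT_CS,
    NULL
  )
}

t_susp_set <- function(index) {
  if (index %in% 8:9) ANY_SUSPICION else CS_SUSPICION
}

build_stages <- function(combination) {
  family <- substr(combination, 1, 1)
  index <- as.integer(substr(combination, 2, 2))
  stages <- list()
  if (family %in% c("M", "N")) {
    stages[[1]] <- new_stage("MPMRI")
    stages[[2]] <- new_stage("TRUSB", trusb_type = 4L,
                             requires = list(req(1L, m_refer_set(index))))
    if (family == "M") {
      trigger <- m_rebiopsy_trigger(index)
      if (!is.null(trigger)) {
        stages[[3]] <- new_stage(
          "TRUSB", trusb_type = 5L,
          requires = list(req(1L, CS_SUSPICION), req(2L, trigger))
        )
      }
    } else {
      stages[[3]] <- new_stage("TPMB", requires_no_cs = TRUE)
    }
  } else if (family %in% c("T", "P")) {
    if (combination == "P1") {
      return(list(new_stage("TPMB")))
    }
    stages[[1]] <- new_stage("TRUSB", trusb_type = 1L)
    if (index %in% 2:4 && family == "T") {
      k <- 2L
      if (index %in% c(2L, 4L)) {
        stages[[k]] <- new_stage("TRUSB", trusb_type = 2L,
                                 requires = list(req(1L, "NC")))
        k <- k + 1L
      }
      if (index %in% c(3L, 4L)) {
        stages[[k]] <- new_stage("TRUSB", trusb_type = 3L,
                                 requires = list(req(1L, "nonCS")))
      }
    } else if (index %in% 2:4 && family == "P") {
      stages[[2]] <- new_stage("TPMB", requires_no_cs = TRUE)
    } else if (index >= 5) {
      stages[[2]] <- new_stage("MPMRI",
                               requires = list(req(1L, t_mri_set(index))))
      if (family == "T") {
        stages[[3]] <- new_stage(
          "TRUSB", trusb_type = 5L,
          requires = list(req(2L, t_susp_set(index)))
        )
      } else {
        stages[[3]] <- new_stage("TPMB", requires_no_cs = TRUE)
      }
    }
  }
  stages
}

# --- strategy construction --------------------------------------------------

new_strategy <- function(combination, histology_definition,
                         mpmri_definition = NA_integer_,
                         mpmri_cutoff = NA_integer_) {
  uses_mpmri <- combination_uses_mpmri(combination)
  label <- if (uses_mpmri) {
    sprintf("%s %d%d%d", combination, histology_definition,
            mpmri_definition, mpmri_cutoff)
  } else {
    sprintf("%s %d", combination, histology_definition)
  }
  stages <- build_stages(combination)
  # bind context parameters into each stage
  stages <- lapply(stages, function(s) {
    s$context <- list(
      test = s$test,
      trusb_type = if (s$test == "TRUSB") s$trusb_type else NA_integer_,
      mpmri_definition = if (s$test == "MPMRI") mpmri_definition
                         else NA_integer_,
      mpmri_cutoff = if (s$test == "MPMRI") mpmri_cutoff else NA_integer_,
      histology_definition = if (s$test == "TRUSB") histology_definition
                             else NA_integer_
    )
    s
  })
  strategy <- structure(
    list(
      label = label, combination = combination,
      family = substr(combination, 1, 1),
      histology_definition = histology_definition,
      mpmri_definition = mpmri_definition,
      mpmri_cutoff = mpmri_cutoff,
      stages = stages
    ),
    class = "dx_strategy"
  )
  validate_strategy(strategy)
  strategy
}

validate_strategy <- function(strategy) {
  stages <- strategy$stages
  if (length(stages) > 3L) {
    # a man receives at most three tests; with disjoint predicates a strategy
    # may declare more stage slots than any one man can trigger
    max_path <- max_tests_per_path(stages)
    if (max_path > 3L) {
      stop("strategy ", strategy$label, " can administer ", max_path,
           " tests to one man; at most 3 are allowed", call. = FALSE)
    }
  }
  ctx_keys <- vapply(stages, function(s) {
    paste(unlist(s$context), collapse = "|")
  }, character(1))
  # identical contexts must be mutually exclusive on any path
  dup <- which(duplicated(ctx_keys))
  for (j in dup) {
    i <- match(ctx_keys[j], ctx_keys)
    if (!stages_disjoint(stages[[i]], stages[[j]])) {
      stop("strategy ", strategy$label,
           " repeats an identical test context on one path", call. = FALSE)
    }
  }
  invisible(strategy)
}

# enumerate class assignments over stages to bound tests per man
max_tests_per_path <- function(stages) {
  n <- length(stages)
  classes <- test_class_levels()
  count_paths <- function(i, results) {
    if (i > n) {
      return(sum(!is.na(results)))
    }
    if (stage_applies(stages[[i]], results, stages)) {
      max(vapply(classes, function(cl) {
        r <- results
        r[i] <- cl
        count_paths(i + 1L, r)
      }, numeric(1)))
    } else {
      count_paths(i + 1L, results)
    }
  }
  count_paths(1L, rep(NA_character_, n))
}

stages_disjoint <- function(a, b) {
  # conservative check: disjoint if they require disjoint result sets of the
  # same earlier stage
  for (ra in a$requires) {
    for (rb in b$requires) {
      if (ra$stage == rb$stage &&
          !length(intersect(ra$result_in, rb$result_in))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# does `stage` apply given the results so far (NA = stage not executed)?
stage_applies <- function(stage, results, stages) {
  for (r in stage$requires) {
    if (is.na(results[r$stage]) || !(results[r$stage] %in% r$result_in)) {
      return(FALSE)
    }
  }
  if (isTRUE(stage$requires_no_cs)) {
    for (j in seq_along(results)) {
      if (!is.na(results[j]) && stages[[j]]$test %in% c("TRUSB", "TPMB") &&
          results[j] == "CS") {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Parse a strategy label
#'
#' @param label A label such as `"M7 222"` or `"P4 2"`: combination code,
#'   a space, then the histology definition digit followed (for combinations
#'   using MPMRI) by the MPMRI definition and cut-off digits.
#'
#' @return A `dx_strategy` object with fully routed stages.
#' @examples
#' parse_strategy_label("M1 125")
#' parse_strategy_label("P4 2")
#' @export
parse_strategy_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- regmatches(label, regexec("^([MNTP][1-9]) ([0-9]+)$", label))[[1]]
  if (!length(m)) {
    stop("cannot parse strategy label ", sQuote(label), call. = FALSE)
  }
  combination <- m[2]
  digits <- m[3]
  if (!combination %in% combination_codes()) {
    stop("unknown combination code ", sQuote(combination), call. = FALSE)
  }
  digit <- as.integer(strsplit(digits, "")[[1]])
  uses_mpmri <- combination_uses_mpmri(combination)
  expected <- if (uses_mpmri) 3L else 1L
  if (length(digit) != expected) {
    stop("combination ", combination, " takes ", expected,
         " digit(s); label ", sQuote(label), " has ", length(digit),
         call. = FALSE)
  }
  if (!digit[1] %in% 1:2) {
    stop("histology definition must be 1 or 2 in ", sQuote(label),
         call. = FALSE)
  }
  if (uses_mpmri) {
    if (!digit[2] %in% 1:2) {
      stop("MPMRI definition must be 1 or 2 in ", sQuote(label),
           call. = FALSE)
    }
    if (!digit[3] %in% 2:5) {
      stop("MPMRI cut-off must be between 2 and 5 in ", sQuote(label),
           call. = FALSE)
    }
    new_strategy(combination, digit[1], digit[2], digit[3])
  } else {
    new_strategy(combination, digit[1])
  }
}

#' Enumerate labelled diagnostic strategies
#'
#' Crosses the 32 test combinations with the applicable variant grid:
#' histology definitions for every combination; MPMRI definitions and
#' cut-offs for the combinations that use imaging. The default grid yields
#' 400 labelled strategies; the published analysis pruned clinically
#' equivalent or infeasible variants to 383 using rules not stated in the
#' main text, so a warning flags the discrepancy (an `exclude` hook lets the
#' caller apply their own pruning).
#'
#' @param combinations Character vector of combination codes to enumerate
#'   (default: all 32).
#' @param histology_definitions,mpmri_definitions Integer subsets of `1:2`.
#' @param mpmri_cutoffs Integer subset of `2:5`.
#' @param exclude Optional predicate `function(strategy)` returning `TRUE`
#'   for strategies to drop.
#' @param warn_grid_size Warn when the default full grid is enumerated
#'   (default `TRUE`).
#'
#' @return A list of `dx_strategy` objects with unique labels.
#' @examples
#' strategies <- enumerate_strategies(warn_grid_size = FALSE)
#' length(strategies)
#' @export
enumerate_strategies <- function(combinations = combination_codes(),
                                 histology_definitions = 1:2,
                                 mpmri_definitions = 1:2,
                                 mpmri_cutoffs = 2:5,
                                 exclude = NULL,
                                 warn_grid_size = TRUE) {
  if (!length(histology_definitions) || !length(mpmri_definitions) ||
      !length(mpmri_cutoffs)) {
    stop("definition and cut-off sets must be non-empty", call. = FALSE)
  }
  stopifnot(all(combinations %in% combination_codes()),
            all(histology_definitions %in% 1:2),
            all(mpmri_definitions %in% 1:2),
            all(mpmri_cutoffs %in% 2:5))
  out <- list()
  for (combination in combinations) {
    if (combination_uses_mpmri(combination)) {
      grid <- expand.grid(h = histology_definitions, d = mpmri_definitions,
                          co = mpmri_cutoffs)
      for (i in seq_len(nrow(grid))) {
        out[[length(out) + 1L]] <-
          new_strategy(combination, grid$h[i], grid$d[i], grid$co[i])
      }
    } else {
      for (h in histology_definitions) {
        out[[length(out) + 1L]] <- new_strategy(combination, h)
      }
    }
  }
  if (!is.null(exclude)) {
    keep <- !vapply(out, exclude, logical(1))
    out <- out[keep]
  }
  labels <- vapply(out, `[[`, character(1), "label")
  stopifnot(!anyDuplicated(labels))
  names(out) <- labels
  full_default <- identical(sort(combinations), sort(combination_codes())) &&
    setequal(histology_definitions, 1:2) && setequal(mpmri_definitions, 1:2) &&
    setequal(mpmri_cutoffs, 2:5) && is.null(exclude)
  if (warn_grid_size && full_default) {
    warning("full variant grid enumerates ", length(out), " strategies; ",
            "the published analysis pruned this to 383 using rules not ",
            "stated in the main text (pass `exclude` to apply your own)",
            call. = FALSE)
  }
  out
}

#' @export
print.dx_strategy <- function(x, ...) {
  cat("<dx_strategy> ", x$label, "\n", sep = "")
  for (i in seq_along(x$stages)) {
    s <- x$stages[[i]]
    ctx <- s$context
    desc <- switch(s$test,
      MPMRI = sprintf("MPMRI (definition %d, cut-off %s)",
                      ctx$mpmri_definition,
                      if (ctx$mpmri_cutoff == 5) "=5"
                      else paste0(">=", ctx$mpmri_cutoff)),
      TRUSB = sprintf("TRUSB type %d (histology definition %d)",
                      ctx$trusb_type, ctx$histology_definition),
      TPMB = "TPMB (reference standard)"
    )
    conds <- vapply(s$requires, function(r) {
      sprintf("stage %d in {%s}", r$stage, paste(r$result_in, collapse = ","))
    }, character(1))
    if (isTRUE(s$requires_no_cs)) conds <- c(conds, "no CS biopsy result yet")
    cat(sprintf("  stage %d: %s%s\n", i, desc,
                if (length(conds)) paste0(" if ", paste(conds, collapse = " & "))
                else ""))
  }
  invisible(x)
}
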