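#' Disease subgroups, test classes and diagnoses
#'
#' The model classifies a man's true disease status into four subgroups:
#' `no_cancer`, `low_risk` (non-clinically-significant cancer),
#' `intermediate_risk` and `high_risk` (the latter two jointly constitute
#' clinically significant, CS, cancer). Every test result is one of three
#' classes: `NC` (no cancer / no suspicion), `nonCS`, or `CS`. A final
#' diagnosis is one of `no_cancer_dx`, `nonCS_dx`, `CS_dx`.
#'
#' @name domain
NULL

#' @rdname domain
#' @return `subgroup_levels()`: the four true-disease subgroups.
#' @export
subgroup_levels <- function() {
  c("no_cancer", "low_risk", "intermediate_risk", "high_risk")
}

#' @rdname domain
#' @return `cs_subgroups()`: the subgroups constituting CS cancer.
#' @export
cs_subgroups <- function() c("intermediate_risk", "high_risk")

#' @rdname domain
#' @return `test_class_levels()`: the three test result classes.
#' @export
test_class_levels <- function() c("NC", "nonCS", "CS")

#' @rdname domain
#' @return `diagnosis_levels()`: the three final diagnoses.
#' @export
diagnosis_levels <- function() c("no_cancer_dx", "nonCS_dx", "CS_dx")

#' @rdname domain
#' @return `test_kinds()`: the three tests.
#' @export
test_kinds <- function() c("MPMRI", "TRUSB", "TPMB")

#' Construct a subgroup prevalence vector
#'
#' @param no_cancer,low_risk,intermediate_risk,high_risk Probabilities of each
#'   true disease subgroup among men referred for testing. Must be in
#'   \[0, 1\] and sum to 1 (within 1e-9).
#'
#' @return A named numeric vector of class `subgroup_prevalence`.
#' @examples
#' subgroup_prevalence(0.3, 0.2, 0.3, 0.2)
#' @export
subgroup_prevalence <- function(no_cancer, low_risk, intermediate_risk,
                                high_risk) {
  p <- c(
    no_cancer = no_cancer, low_risk = low_risk,
    intermediate_risk = intermediate_risk, high_risk = high_risk
  )
  validate_prevalence(p)
  structure(p, class = "subgroup_prevalence")
}

validate_prevalence <- function(p) {
  if (!is.numeric(p) || length(p) != 4L ||
      !identical(names(p), subgroup_levels())) {
    stop("prevalence must be a numeric vector named ",
         paste(subgroup_levels(), collapse = ", "), call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop("prevalence entries must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("prevalence must sum to 1 (got ", format(sum(p), digits = 12), ")",
         call. = FALSE)
  }
  invisible(p)
}

# severity ranking used by the diagnosis rule: CS > nonCS > NC
class_severity <- function(classes) {
  match(classes, test_class_levels())
}

severity_to_diagnosis <- function(max_severity) {
  diagnosis_levels()[max_severity]
}
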