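#' Test-performance tables
#'
#' A performance table stores, for every test context and true disease
#' subgroup, the probability that the test classifies the man as `NC`,
#' `nonCS` or `CS`. A *test context* identifies the test and the situation in
#' which it is applied:
#'
#' * `TRUSB` contexts carry a `trusb_type` (1-5) encoding history dependence:
#'   1 = first TRUSB before any MPMRI; 2 = repeat TRUSB after a TRUSB that
#'   detected no cancer; 3 = repeat TRUSB after a TRUSB that detected non-CS
#'   cancer; 4 = MRI-targeted TRUSB after a suspicious MPMRI; 5 = MRI-targeted
#'   repeat TRUSB after a prior TRUSB and a suspicious MPMRI. TRUSB rows also
#'   carry the histological CS-cancer definition (1 or 2).
#' * `MPMRI` contexts carry the imaging CS definition (1 or 2) and the Likert
#'   suspicion cut-off (2, 3, 4 = "at or above", 5 = "equal to 5") already
#'   applied, so each row is the post-cut-off classification distribution.
#' * `TPMB` is the reference standard: it maps truth to result exactly.
#'
#' Biopsies cannot detect cancer in cancer-free men, so every TRUSB row for
#' the `no_cancer` subgroup is (NC = 1, 0, 0); these rows (and the TPMB
#' identity rows) are generated rather than transcribed.
#'
#' @name performance_table
NULL

perf_columns <- function() {
  c("test", "trusb_type", "mpmri_definition", "mpmri_cutoff",
    "histology_definition", "subgroup", "p_nc", "p_noncs", "p_cs")
}

#' Build a test-performance table
#'
#' @param df A data frame with columns `test`, `trusb_type`,
#'   `mpmri_definition`, `mpmri_cutoff`, `histology_definition`, `subgroup`,
#'   `p_nc`, `p_noncs`, `p_cs`. Context fields that do not apply to a test are
#'   `NA`.
#' @param renormalise If `TRUE` (default), rows whose probabilities do not sum
#'   to 1 within `1e-9` are divided by their row total (printed tables can be
#'   off by rounding); a message lists the adjusted rows. If `FALSE`, such
#'   rows are an error.
#'
#' @return A data frame of class `perf_table`, row-stochastic within `1e-9`.
#' @export
performance_table <- function(df, renormalise = TRUE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(perf_columns(), names(df))
  if (length(missing_cols)) {
    stop("performance table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[perf_columns()]
  if (!all(df$test %in% test_kinds())) {
    stop("unknown test kind in performance table", call. = FALSE)
  }
  if (!all(df$subgroup %in% subgroup_levels())) {
    stop("unknown subgroup in performance table", call. = FALSE)
  }
  probs <- as.matrix(df[, c("p_nc", "p_noncs", "p_cs")])
  if (any(probs < 0 | probs > 1)) {
    stop("classification probabilities must lie in [0, 1]", call. = FALSE)
  }
  tot <- rowSums(probs)
  off <- which(abs(tot - 1) > 1e-9)
  if (length(off)) {
    if (!renormalise) {
      stop("rows ", paste(off, collapse = ", "),
           " do not sum to 1; set renormalise = TRUE to rescale",
           call. = FALSE)
    }
    probs[off, ] <- probs[off, , drop = FALSE] / tot[off]
    df[, c("p_nc", "p_noncs", "p_cs")] <- probs
    message(length(off), " performance row(s) renormalised to sum to 1")
  }
  # biopsy rows for cancer-free men must be deterministic NC
  biopsy_noc <- df$test %in% c("TRUSB", "TPMB") & df$subgroup == "no_cancer"
  bad <- biopsy_noc & (df$p_nc != 1 | df$p_noncs != 0 | df$p_cs != 0)
  if (any(bad)) {
    stop("TRUSB/TPMB rows for the no_cancer subgroup must be (1, 0, 0): ",
         "a biopsy cannot detect cancer in cancer-free men", call. = FALSE)
  }
  key <- perf_key(df$test, df$trusb_type, df$mpmri_definition,
                  df$mpmri_cutoff, df$histology_definition, df$subgroup)
  if (anyDuplicated(key)) {
    stop("duplicated (context, subgroup) rows in performance table",
         call. = FALSE)
  }
  rownames(df) <- key
  class(df) <- c("perf_table", "data.frame")
  df
}

perf_key <- function(test, trusb_type, mpmri_definition, mpmri_cutoff,
                     histology_definition, subgroup) {
  paste(test, trusb_type, mpmri_definition, mpmri_cutoff,
        histology_definition, subgroup, sep = "|")
}

# fast lookup list: key -> c(NC, nonCS, CS)
perf_lookup <- function(perf) {
  m <- as.matrix(perf[, c("p_nc", "p_noncs", "p_cs")])
  dimnames(m) <- list(rownames(perf), test_class_levels())
  m
}

perf_row <- function(lookup, context, subgroup) {
  key <- perf_key(context$test, context$trusb_type, context$mpmri_definition,
                  context$mpmri_cutoff, context$histology_definition, subgroup)
  if (!key %in% rownames(lookup)) {
    stop("performance table has no row for context ", key, call. = FALSE)
  }
  lookup[key, ]
}

# rows generated in code: TPMB reference-standard identity and
# TRUSB no-cancer rows for every (type, histology definition)
reference_rows <- function(histology_definitions = 1:2, trusb_types = 1:5) {
  tpmb_class <- c(
    no_cancer = "NC", low_risk = "nonCS",
    intermediate_risk = "CS", high_risk = "CS"
  )
  tpmb <- do.call(rbind, lapply(names(tpmb_class), function(sg) {
    data.frame(
      test = "TPMB", trusb_type = NA_integer_,
      mpmri_definition = NA_integer_, mpmri_cutoff = NA_integer_,
      histology_definition = NA_integer_, subgroup = sg,
      p_nc = as.numeric(tpmb_class[[sg]] == "NC"),
      p_noncs = as.numeric(tpmb_class[[sg]] == "nonCS"),
      p_cs = as.numeric(tpmb_class[[sg]] == "CS")
    )
  }))
  grid <- expand.grid(type = trusb_types, def = histology_definitions)
  trusb_noc <- data.frame(
    test = "TRUSB", trusb_type = grid$type,
    mpmri_definition = NA_integer_, mpmri_cutoff = NA_integer_,
    histology_definition = grid$def, subgroup = "no_cancer",
    p_nc = 1, p_noncs = 0, p_cs = 0
  )
  rbind(tpmb, trusb_noc)
}

#' Load the packaged test-performance tables
#'
#' Returns the transcription of the published subgroup-conditional
#' classification probabilities: TRUSB types 1-5 under histology definitions
#' 1-2, and MPMRI under imaging definitions 1-2 at suspicion cut-offs 2-5.
#' TPMB reference-standard rows and TRUSB no-cancer rows are appended in code.
#'
#' Two printed MPMRI rows sum to 0.99 and 1.01 because of rounding in the
#' source; with `renormalise = TRUE` (default) they are rescaled to sum to 1.
#'
#' @param renormalise Passed to [performance_table()].
#' @return A `perf_table`.
#' @examples
#' perf <- packaged_performance_tables()
#' @export
packaged_performance_tables <- function(renormalise = TRUE) {
  trusb <- utils::read.csv(
    system.file("extdata", "trusb_performance.csv", package = "pathcea"),
    colClasses = c("integer", "integer", "character",
                   "numeric", "numeric", "numeric")
  )
  trusb$test <- "TRUSB"
  trusb$mpmri_definition <- NA_integer_
  trusb$mpmri_cutoff <- NA_integer_
  mpmri <- utils::read.csv(
    system.file("extdata", "mpmri_performance.csv", package = "pathcea"),
    colClasses = c("integer", "integer", "character",
                   "numeric", "numeric", "numeric")
  )
  mpmri$test <- "MPMRI"
  mpmri$trusb_type <- NA_integer_
  mpmri$histology_definition <- NA_integer_
  df <- rbind(
    trusb[perf_columns()], mpmri[perf_columns()], reference_rows()
  )
  performance_table(df, renormalise = renormalise)
}
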