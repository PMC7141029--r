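#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter arrange select bind_rows left_join desc
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_int
NULL

# Columns of a coverage table that carry sample metadata, not promoter values.
.meta_cols <- c("sample_id", "label", "cohort", "bmi", "gestational_age")

#' Promoter feature columns of a coverage table
#'
#' A coverage table (see [build_coverage_matrix()]) is a wide tibble with one
#' row per sample: the reserved metadata columns (`sample_id`, `label`,
#' `cohort`, `bmi`, `gestational_age`) followed by one RPKM column per pTSS
#' window. This helper returns the window column names.
#'
#' @param cov a coverage tibble.
#' @return character vector of feature (window) column names.
#' @export
coverage_features <- function(cov) {
  setdiff(names(cov), .meta_cols)
}

# Numeric matrix (samples x windows) view of a coverage tibble.
.cov_values <- function(cov, features = NULL) {
  features <- features %||% coverage_features(cov)
  m <- as.matrix(cov[, features, drop = FALSE])
  rownames(m) <- cov$sample_id
  storage.mode(m) <- "double"
  m
}

# Case indicator from a label column; errors unless both classes are present
# (unless require_both = FALSE).
.case_indicator <- function(labels, require_both = TRUE) {
  if (is.logical(labels)) {
    y <- labels
  } else if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      abort("numeric labels must be 0/1")
    }
    y <- labels == 1
  } else {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("case", "control"))
    if (length(bad) > 0) {
      abort(paste0("labels must be 'case'/'control', found: ",
                   paste(bad, collapse = ", ")))
    }
    y <- labels == "case"
  }
  if (any(is.na(y))) abort("labels contain missing values")
  if (require_both && (!any(y) || all(y))) {
    abort("both classes (case and control) must be present")
  }
  y
}

# Candidate cutpoints for threshold searches: midpoints between consecutive
# sorted unique values, plus one candidate below the minimum and one above
# the maximum.
.candidate_cutpoints <- function(values) {
  u <- sort(unique(values))
  if (length(u) == 1) {
    return(c(u - 1, u + 1))
  }
  c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
}

.check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
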