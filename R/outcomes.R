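#' Label moderate/severe negative-symptom outcome from follow-up SIPS-N items
#'
#' Implements the clinical labelling rule for negative-symptom severity: a
#' subject has a moderate/severe ("bad") outcome if any of the five follow-up
#' SIPS negative-symptom items N1 (social anhedonia), N2 (avolition), N3
#' (expression of emotion), N4 (experience of emotions and self) or N6
#' (occupational functioning) is rated 3 or higher. Item N5 (ideational
#' richness) is deliberately not part of the rule and must not be supplied.
#'
#' @param items Either a `cohort_table` (the five `sips_n*_t1` columns are
#'   used), or a numeric vector of the five item scores for one subject, or a
#'   matrix/data.frame with five columns (one row per subject). All scores must
#'   be integers in 0..6.
#' @return Integer vector of 0/1 labels (1 = moderate/severe outcome).
#' @examples
#' label_negative_symptoms(c(2, 2, 2, 3, 2))  # 1: one item at threshold
#' label_negative_symptoms(c(2, 2, 2, 2, 2))  # 0: all mild
#' @export
label_negative_symptoms <- function(items) {
  if (inherits(items, "cohort_table") ||
      (is.data.frame(items) && all(sips_t1_cols %in% names(items)))) {
    items <- as.matrix(as.data.frame(items)[, sips_t1_cols])
  }
  if (is.vector(items) && !is.list(items)) items <- matrix(items, nrow = 1L)
  items <- as.matrix(items)
  if (ncol(items) != 5L) {
    stop("expected exactly 5 SIPS-N items (N1, N2, N3, N4, N6), got ", ncol(items))
  }
  if (anyNA(items) || !is.numeric(items)) stop("SIPS-N items must be numeric and non-missing")
  if (any(items != round(items)) || any(items < 0) || any(items > 6)) {
    stop("SIPS-N items must be integers in 0..6")
  }
  as.integer(apply(items, 1L, max) >= 3)
}

#' Label impaired functioning from a Global Functioning score
#'
#' Dichotomizes Global Functioning Social/Role scores (1..10) into adequate
#' (more than 7 points, label 0) vs impaired (7 or fewer points, label 1).
#'
#' @param gf_score Integer vector of scores in 1..10.
#' @return Integer vector of 0/1 impairment flags.
#' @examples
#' label_functioning(c(8, 7, 1))  # 0 1 1
#' @export
label_functioning <- function(gf_score) {
  if (anyNA(gf_score) || !is.numeric(gf_score)) stop("GF scores must be numeric and non-missing")
  if (any(gf_score != round(gf_score)) || any(gf_score < 1) || any(gf_score > 10)) {
    stop("GF scores must be integers in 1..10")
  }
  as.integer(gf_score <= 7)
}

#' Add outcome label columns to a cohort table
#'
#' Appends `negsym_bad`, `gf_social_impaired` and `gf_role_impaired` binary
#' columns computed with [label_negative_symptoms()] and [label_functioning()].
#' Subjects with incomplete follow-up items are not permitted (the pipeline is
#' a complete-case analysis); missing values raise an error.
#'
#' @param cohort A `cohort_table`.
#' @return The cohort with three additional integer label columns.
#' @export
add_outcome_labels <- function(cohort) {
  cohort$negsym_bad <- label_negative_symptoms(cohort)
  cohort$gf_social_impaired <- label_functioning(cohort$gf_social_t1)
  cohort$gf_role_impaired <- label_functioning(cohort$gf_role_t1)
  cohort
}
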