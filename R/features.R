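#' Normalize gyrification ROI values for intracranial volume
#'
#' Divides out the proportional dependence of regional gyrification on head
#' size: each subject's ROI values are multiplied by
#' `reference_icv / icv`, where `reference_icv` is the mean intracranial volume
#' of the training partition (never of the subjects being transformed, to keep
#' test folds untouched by training statistics).
#'
#' @param roi_values Numeric vector (one subject) or matrix (subjects x ROIs).
#' @param icv Positive intracranial volume(s), mm^3; length 1 or one per row.
#' @param reference_icv Positive scalar, the training-cohort mean ICV.
#' @return Normalized values, same shape as `roi_values`.
#' @examples
#' normalize_by_icv(2.5, icv = 1.6e6, reference_icv = 1.5e6)  # 2.34375
#' @export
normalize_by_icv <- function(roi_values, icv, reference_icv) {
  if (any(icv <= 0) || !all(is.finite(icv))) stop("icv must be positive and finite")
  if (length(reference_icv) != 1L || reference_icv <= 0 || !is.finite(reference_icv)) {
    stop("reference_icv must be a positive finite scalar")
  }
  if (is.matrix(roi_values)) {
    if (length(icv) != 1L && length(icv) != nrow(roi_values)) {
      stop("icv must have length 1 or one value per row")
    }
    roi_values * (reference_icv / icv)
  } else {
    roi_values * (reference_icv / icv)
  }
}

#' Fit a per-feature z-standardization on a training partition
#'
#' Estimates per-column location (mean) and scale (population SD, divisor n)
#' on training rows only. Applying the fitted parameters to the training matrix
#' yields exact column means 0 and SDs 1; test partitions are transformed with
#' the training parameters unchanged, so no information leaks across folds.
#' Zero-variance features are flagged and scaled by 1 with a warning.
#'
#' @param train Numeric matrix, subjects x features, at least 2 rows.
#' @return An object of class `scaler_params` with `center`, `scale` and a
#'   logical `degenerate` flag per feature.
#' @export
fit_scaler <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 2L) stop("scaler needs at least 2 training rows")
  if (!all(is.finite(train))) stop("non-finite feature values in training partition")
  center <- colMeans(train)
  scale <- sqrt(colMeans(sweep(train, 2L, center)^2))  # population SD
  degenerate <- scale <= 0
  if (any(degenerate)) {
    warning("zero-variance feature(s) scaled by 1: ",
            paste(colnames(train)[degenerate], collapse = ", "))
    scale[degenerate] <- 1
  }
  structure(list(center = center, scale = scale, degenerate = degenerate),
            class = "scaler_params")
}

#' Apply fitted standardization parameters
#'
#' @param params A `scaler_params` from [fit_scaler()].
#' @param X Numeric matrix with the same number of columns.
#' @return The standardized matrix.
#' @export
apply_scaler <- function(params, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$center)) {
    stop("feature count mismatch: scaler has ", length(params$center),
         " features, input has ", ncol(X))
  }
  sweep(sweep(X, 2L, params$center), 2L, params$scale, "/")
}

#' Assemble a predictor matrix for one feature view
#'
#' Extracts one of the two predictor views from a cohort table: the five
#' baseline SIPS-N items (`"sips_n"`) or the 68 gyrification ROI columns
#' (`"gyrification"`). ICV normalization and scaling are not applied here; they
#' are fold-local operations performed inside the cross-validation loop.
#'
#' @param cohort A `cohort_table` (or data.frame with the required columns).
#' @param view `"sips_n"` or `"gyrification"`.
#' @return A list with `X` (numeric matrix), `feature_names`, `subject_ids`,
#'   `view`, and for the gyrification view the `icv` vector.
#' @export
feature_matrix <- function(cohort, view = c("sips_n", "gyrification")) {
  view <- match.arg(view)
  cols <- switch(view, sips_n = sips_t0_cols, gyrification = roi_names())
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required feature column(s): ",
         paste(utils::head(missing_cols, 5L), collapse = ", "))
  }
  X <- as.matrix(as.data.frame(cohort)[, cols])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("non-finite values in feature view '", view, "'")
  list(X = X, feature_names = cols, subject_ids = cohort$subject_id,
       view = view,
       icv = if (view == "gyrification") cohort$icv else NULL)
}
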