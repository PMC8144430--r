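#' Cross-validation-ratio (CVR) feature importance
#'
#' Summarizes the stability and direction of each feature's contribution
#' across the fold-wise linear decision functions: each weight vector is first
#' normalized to unit Euclidean norm, then per feature
#' `CVR = mean(w) / SE(w)` with `SE(w) = sd(w)/sqrt(K)` (sample SD, divisor
#' K-1) over the K vectors. Negative CVRs indicate that reduced values of the
#' predictor are associated with increased risk of the bad outcome; positive
#' values that larger predictor values increase risk. Features are ranked by
#' `|CVR|`; features identical across folds (SE = 0) are flagged and excluded
#' from the ranking instead of reported as infinite.
#'
#' @param weights Either an `lso_fit` (all retained ensemble members across
#'   outer folds are pooled; see [weight_matrix()]) or a numeric K x F matrix
#'   of fold-wise weight vectors, K >= 2.
#' @param normalize Normalize each weight vector to unit L2 norm first
#'   (disable for pre-normalized inputs).
#' @return Data frame of class `cvr_profile`: `feature`, `mean_w`, `se_w`,
#'   `cvr`, `rank` (NA for flagged features), `flagged`.
#' @examples
#' w <- matrix(c(0.10, 0.20, 0.15, 0.12, 0.18), ncol = 1)
#' cvr_profile(w, normalize = FALSE)$cvr  # ~ 8.13
#' @export
cvr_profile <- function(weights, normalize = TRUE) {
  if (inherits(weights, "lso_fit")) {
    W <- weight_matrix(weights, normalize = FALSE)
  } else {
    W <- as.matrix(weights)
  }
  K <- nrow(W)
  if (K < 2L) stop("CVR needs at least 2 fold-wise weight vectors")
  if (!all(is.finite(W))) stop("non-finite weights")
  if (normalize) {
    nrm <- sqrt(rowSums(W^2))
    if (any(nrm == 0)) stop("cannot unit-normalize an all-zero weight vector")
    W <- W / nrm
  }
  mean_w <- colMeans(W)
  se_w <- apply(W, 2L, stats::sd) / sqrt(K)
  flagged <- se_w == 0
  cvr <- ifelse(flagged, NA_real_, mean_w / se_w)
  out <- data.frame(
    feature = colnames(W) %||% paste0("f", seq_len(ncol(W))),
    mean_w = mean_w, se_w = se_w, cvr = cvr,
    rank = NA_integer_, flagged = flagged,
    stringsAsFactors = FALSE, row.names = NULL)
  ok <- which(!flagged)
  out$rank[ok[order(-abs(cvr[ok]))]] <- seq_along(ok)
  class(out) <- c("cvr_profile", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top-ranked features of a CVR profile
#'
#' @param profile A `cvr_profile`.
#' @param n Number of features.
#' @return The `n` rows with smallest rank, ordered by rank.
#' @export
top_features <- function(profile, n = 10L) {
  p <- profile[!is.na(profile$rank), , drop = FALSE]
  p[order(p$rank), , drop = FALSE][seq_len(min(n, nrow(p))), , drop = FALSE]
}

#' @export
print.cvr_profile <- function(x, n = 10L, ...) {
  cat(sprintf("CVR profile over %d features (top %d by |CVR|):\n",
              nrow(x), min(n, sum(!is.na(x$rank)))))
  tf <- top_features(x, n)
  print(data.frame(feature = tf$feature, mean_w = signif(tf$mean_w, 3),
                   se_w = signif(tf$se_w, 3), cvr = round(tf$cvr, 2),
                   rank = tf$rank), row.names = FALSE)
  if (any(x$flagged)) {
    cat("flagged (zero SE, excluded from ranking): ",
        paste(x$feature[x$flagged], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bar plot of the top-N CVR features
#'
#' @param x A `cvr_profile`.
#' @param n Number of features to show.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.cvr_profile <- function(x, n = 10L, ...) {
  tf <- top_features(x, n)
  graphics::barplot(rev(tf$cvr), names.arg = rev(tf$feature), horiz = TRUE,
                    las = 1, xlab = "CVR = mean(w) / SE(w)",
                    main = sprintf("Top %d features by |CVR|", nrow(tf)), ...)
  invisible(x)
}
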