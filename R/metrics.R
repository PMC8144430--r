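#' Confusion counts from predicted and true binary labels
#'
#' Positive class = bad outcome (label 1).
#'
#' @param pred Predicted 0/1 labels.
#' @param y True 0/1 labels.
#' @return List of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(pred, y) {
  stopifnot(length(pred) == length(y))
  pred <- as.integer(pred); y <- as.integer(y)
  if (!all(pred %in% 0:1) || !all(y %in% 0:1)) stop("labels must be binary 0/1")
  structure(list(TP = sum(pred == 1 & y == 1), FP = sum(pred == 1 & y == 0),
                 TN = sum(pred == 0 & y == 0), FN = sum(pred == 0 & y == 1)),
            class = "confusion_counts")
}

#' Point classification metrics from confusion counts
#'
#' Sensitivity SE = TP/(TP+FN), specificity SP = TN/(TN+FP), positive and
#' negative predictive values, and balanced accuracy BAC = (SE+SP)/2. PPV/NPV
#' with an empty denominator are returned as `NA` with a flag rather than
#' failing, since a degenerate classifier can legitimately predict one class
#' only.
#'
#' @param counts A `confusion_counts` or list with `TP`, `FP`, `TN`, `FN`.
#' @return List of class `point_metrics`: `SE`, `SP`, `PPV`, `NPV`, `BAC`,
#'   `counts`, and `undefined` (names of metrics with empty denominators).
#' @examples
#' m <- point_metrics(list(TP = 18, FP = 6, TN = 50, FN = 20))
#' round(100 * c(m$SE, m$SP, m$PPV, m$NPV, m$BAC))  # 47 89 75 71 68
#' @export
point_metrics <- function(counts) {
  k <- lapply(counts[c("TP", "FP", "TN", "FN")], as.numeric)
  if (any(vapply(k, function(x) is.na(x) || x < 0 || x != round(x), logical(1)))) {
    stop("confusion counts must be non-negative integers")
  }
  if (k$TP + k$FN == 0) stop("no subjects in the positive class")
  if (k$TN + k$FP == 0) stop("no subjects in the negative class")
  se <- k$TP / (k$TP + k$FN)
  sp <- k$TN / (k$TN + k$FP)
  undefined <- character(0)
  ppv <- if (k$TP + k$FP > 0) k$TP / (k$TP + k$FP) else { undefined <- c(undefined, "PPV"); NA_real_ }
  npv <- if (k$TN + k$FN > 0) k$TN / (k$TN + k$FN) else { undefined <- c(undefined, "NPV"); NA_real_ }
  structure(list(SE = se, SP = sp, PPV = ppv, NPV = npv, BAC = (se + sp) / 2,
                 counts = counts, undefined = undefined),
            class = "point_metrics")
}

#' Area under the ROC curve (Mann-Whitney rank formulation)
#'
#' AUC as the probability that a random positive subject's decision score
#' exceeds a random negative subject's, with ties contributing 1/2; computed
#' via the rank-sum identity.
#'
#' @param scores Numeric decision scores (higher = more likely bad outcome).
#' @param y True 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, y) {
  y <- as.integer(y)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC requires both outcome classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Posterior distribution of balanced accuracy
#'
#' Bayesian inference on balanced accuracy from pooled confusion counts.
#' Sensitivity and specificity receive independent conjugate Beta posteriors,
#' `SE ~ Beta(TP + a, FN + b)` and `SP ~ Beta(TN + a, FP + b)`; the posterior
#' of BAC = (SE + SP)/2 is their convolution, computed either by numerical
#' convolution of the two Beta densities on a fine grid (default,
#' deterministic) or by Monte Carlo. A model is declared significantly better
#' than chance when at least 95\% of the posterior mass lies above BAC = 0.5.
#'
#' @param counts A `confusion_counts` (or compatible list).
#' @param prior Length-2 Beta prior `c(a, b)`; default flat `c(1, 1)`
#'   (`prior = "jeffreys"` gives `c(0.5, 0.5)`).
#' @param method `"grid_convolution"` (default) or `"monte_carlo"`.
#' @param n_draws Monte Carlo draws (ignored for the grid method).
#' @param seed Seed for the Monte Carlo method.
#' @param grid_n Grid resolution per Beta margin for the convolution method.
#' @return List of class `bac_posterior`: `mean`, `ci` (central 95\% credible
#'   interval), `mass_above_0.5`, `significant`, plus method/prior metadata.
#' @examples
#' posterior_bac(list(TP = 18, FP = 6, TN = 50, FN = 20))
#' @export
posterior_bac <- function(counts, prior = c(1, 1),
                          method = c("grid_convolution", "monte_carlo"),
                          n_draws = 1e5, seed = 1L, grid_n = 4096L) {
  method <- match.arg(method)
  if (identical(prior, "jeffreys")) prior <- c(0.5, 0.5)
  if (!is.numeric(prior) || length(prior) != 2L || any(prior <= 0)) {
    stop("prior must be two positive Beta parameters")
  }
  k <- lapply(counts[c("TP", "FP", "TN", "FN")], as.numeric)
  a_se <- k$TP + prior[1]; b_se <- k$FN + prior[2]
  a_sp <- k$TN + prior[1]; b_sp <- k$FP + prior[2]

  if (method == "grid_convolution") {
    # discretize each Beta on midpoints, convolve the two pmfs, halve the support
    x <- (seq_len(grid_n) - 0.5) / grid_n
    p_se <- stats::dbeta(x, a_se, b_se); p_se <- p_se / sum(p_se)
    p_sp <- stats::dbeta(x, a_sp, b_sp); p_sp <- p_sp / sum(p_sp)
    pmf <- stats::convolve(p_se, rev(p_sp), type = "open")  # support: sum index 2..2*grid_n
    pmf[pmf < 0] <- 0                                        # FFT round-off
    pmf <- pmf / sum(pmf)
    # convolved index k corresponds to SE+SP = k/grid_n (midpoint grids), so
    bac_grid <- seq_along(pmf) / (2 * grid_n)
    post_mean <- sum(bac_grid * pmf)
    cdf <- cumsum(pmf)
    qfun <- function(q) bac_grid[which.max(cdf >= q)]
    ci <- c(qfun(0.025), qfun(0.975))
    mass <- sum(pmf[bac_grid > 0.5])
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({ if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) })
    set.seed(seed)
    draws <- (stats::rbeta(n_draws, a_se, b_se) + stats::rbeta(n_draws, a_sp, b_sp)) / 2
    post_mean <- mean(draws)
    ci <- unname(stats::quantile(draws, c(0.025, 0.975), type = 7))
    mass <- mean(draws > 0.5)
  }
  structure(list(mean = post_mean, ci = ci, mass_above_0.5 = mass,
                 significant = mass >= 0.95, method = method, prior = prior,
                 counts = counts),
            class = "bac_posterior")
}

#' Full performance report for out-of-fold decision scores
#'
#' Combines confusion counts, point metrics, AUC and the posterior-BAC summary
#' into one report, mirroring a classification-performance table row
#' (BAC, AUC, SE, SP, PPV, NPV).
#'
#' @param scores Numeric decision scores (threshold 0 gives predicted labels
#'   unless `pred` is supplied).
#' @param y True 0/1 labels.
#' @param pred Optional explicit predicted labels.
#' @param prior,posterior_method Passed to [posterior_bac()].
#' @return List of class `performance_report`.
#' @export
performance_report <- function(scores, y, pred = scores > 0,
                               prior = c(1, 1),
                               posterior_method = "grid_convolution") {
  counts <- confusion_counts(as.integer(pred), y)
  pm <- point_metrics(counts)
  post <- posterior_bac(counts, prior = prior, method = posterior_method)
  structure(list(counts = counts, metrics = pm, auc = auc_mw(scores, y),
                 posterior = post, n = length(y)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "Performance (n = %d, positives = %d)\n  BAC %.3f%s  AUC %.3f  SE %.3f  SP %.3f  PPV %s  NPV %s\n",
    x$n, x$counts$TP + x$counts$FN, m$BAC,
    if (x$posterior$significant) "*" else " ", x$auc, m$SE, m$SP,
    ifelse(is.na(m$PPV), "NA", sprintf("%.3f", m$PPV)),
    ifelse(is.na(m$NPV), "NA", sprintf("%.3f", m$NPV))))
  cat(sprintf("  integer percents: BAC %d | AUC %d | SE %d | SP %d | PPV %s | NPV %s\n",
              round(100 * m$BAC), round(100 * x$auc), round(100 * m$SE), round(100 * m$SP),
              ifelse(is.na(m$PPV), "NA", round(100 * m$PPV)),
              ifelse(is.na(m$NPV), "NA", round(100 * m$NPV))))
  cat(sprintf("  posterior BAC %.3f [%.3f, %.3f], P(BAC > 0.5) = %.4f%s\n",
              x$posterior$mean, x$posterior$ci[1], x$posterior$ci[2],
              x$posterior$mass_above_0.5,
              if (x$posterior$significant) "  (significant)" else ""))
  invisible(x)
}
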