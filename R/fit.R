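# Internal machinery shared by fit_lso() and fit_stacked(): fit the ensemble of
# linear decision functions for one outer fold, selecting the regularization
# strength by inner CV and retaining all inner-loop models at the winner.

.inv_prev_weights <- function(y) {
  prev <- mean(y)
  w <- ifelse(y == 1, 1 / (2 * prev), 1 / (2 * (1 - prev)))
  w / mean(w)
}

# One preprocessing context: optional ICV ratio normalization (reference = the
# member's training-mean ICV) followed by optional z-standardization.
.fit_preproc <- function(Xraw, icv, idx, use_icv, scale_features) {
  ref_icv <- if (use_icv) mean(icv[idx]) else NA_real_
  Xn <- if (use_icv) normalize_by_icv(Xraw[idx, , drop = FALSE], icv[idx], ref_icv)
        else Xraw[idx, , drop = FALSE]
  scaler <- if (scale_features) suppressWarnings(fit_scaler(Xn)) else NULL
  list(ref_icv = ref_icv, scaler = scaler)
}

.apply_preproc <- function(pp, Xraw, icv, idx) {
  Xn <- if (!is.na(pp$ref_icv)) {
    normalize_by_icv(Xraw[idx, , drop = FALSE], icv[idx], pp$ref_icv)
  } else Xraw[idx, , drop = FALSE]
  if (!is.null(pp$scaler)) apply_scaler(pp$scaler, Xn) else Xn
}

# Fit linear models for every grid value on standardized training data.
# Returns list of (w, b) per grid value; grid is a decreasing regularization
# strength lambda (logistic) mapped to cost = 1/lambda for the hinge loss.
.fit_linear_grid <- function(Z, yv, wts, grid, loss) {
  p <- ncol(Z)
  if (loss == "logistic") {
    # glmnet prefers a path; pad a single-lambda grid with a larger lead value
    path <- if (length(grid) == 1L) c(grid * 10, grid) else grid
    fit <- glmnet::glmnet(Z, yv, family = "binomial", alpha = 0,
                          lambda = path, weights = wts,
                          standardize = FALSE, intercept = TRUE)
    lapply(seq_along(grid), function(j) {
      k <- match(grid[j], fit$lambda)
      list(w = as.numeric(fit$beta[, k]), b = as.numeric(fit$a0[k]))
    })
  } else {
    yfac <- factor(yv, levels = c(0, 1))
    cw <- c("0" = 1, "1" = 1)
    if (!is.null(wts)) {
      cw <- c("0" = wts[match(0, yv)], "1" = wts[match(1, yv)])
    }
    lapply(grid, function(lam) {
      m <- e1071::svm(Z, yfac, kernel = "linear", cost = 1 / lam,
                      scale = FALSE, class.weights = cw)
      w <- as.numeric(crossprod(m$coefs, m$SV))
      b <- -m$rho
      # libsvm orients the decision value toward the first class seen in the
      # training data; flip so positive scores always favour class "1"
      pair <- colnames(attr(stats::predict(m, Z[1, , drop = FALSE],
                                           decision.values = TRUE),
                            "decision.values"))
      if (identical(pair, "0/1")) { w <- -w; b <- -b }
      list(w = w, b = b)
    })
  }
}

.fold_bac <- function(score, yv) {
  pred <- as.integer(score > 0)
  parts <- c(if (any(yv == 1)) mean(pred[yv == 1] == 1),
             if (any(yv == 0)) mean(pred[yv == 0] == 0))
  mean(parts)
}

.train_one_outer <- function(Xraw, icv, y, inner, grid, loss, balance,
                             use_icv, scale_features, ensemble) {
  n <- nrow(Xraw)
  inner_r <- ncol(inner)
  grid <- sort(grid, decreasing = TRUE)
  if (max(inner) < 2L) {
    # degenerate single-split mode: no inner validation possible
    if (length(grid) != 1L) {
      stop("inner_k = 1 admits no hyperparameter selection; supply a grid of size 1")
    }
    pp <- .fit_preproc(Xraw, icv, seq_len(n), use_icv, scale_features)
    Z <- .apply_preproc(pp, Xraw, icv, seq_len(n))
    wts <- if (balance) .inv_prev_weights(y) else rep(1, n)
    mod <- .fit_linear_grid(Z, y, wts, grid, loss)[[1]]
    member <- list(w = mod$w, b = mod$b, ref_icv = pp$ref_icv,
                   scaler = pp$scaler, lambda = grid)
    return(list(members = list(member), lambda = grid,
                inner_bac = stats::setNames(NA_real_, grid)))
  }

  bac <- matrix(NA_real_, 0L, length(grid))
  cand <- vector("list", 0L)
  for (r in seq_len(inner_r)) {
    fold <- inner[, r]
    for (f in sort(unique(fold))) {
      it <- which(fold != f); iv <- which(fold == f)
      pp <- .fit_preproc(Xraw, icv, it, use_icv, scale_features)
      Zt <- .apply_preproc(pp, Xraw, icv, it)
      Zv <- .apply_preproc(pp, Xraw, icv, iv)
      wts <- if (balance) .inv_prev_weights(y[it]) else rep(1, length(it))
      mods <- .fit_linear_grid(Zt, y[it], wts, grid, loss)
      bac <- rbind(bac, vapply(mods, function(m) {
        .fold_bac(as.numeric(Zv %*% m$w + m$b), y[iv])
      }, numeric(1)))
      cand[[length(cand) + 1L]] <- list(pp = pp, mods = mods)
    }
  }
  mean_bac <- colMeans(bac)
  win <- which.max(mean_bac)  # ties resolve toward stronger regularization
  lambda <- grid[win]

  if (ensemble == "refit") {
    pp <- .fit_preproc(Xraw, icv, seq_len(n), use_icv, scale_features)
    Z <- .apply_preproc(pp, Xraw, icv, seq_len(n))
    wts <- if (balance) .inv_prev_weights(y) else rep(1, n)
    mod <- .fit_linear_grid(Z, y, wts, lambda, loss)[[1]]
    members <- list(list(w = mod$w, b = mod$b, ref_icv = pp$ref_icv,
                         scaler = pp$scaler, lambda = lambda))
  } else {
    members <- lapply(cand, function(cc) {
      list(w = cc$mods[[win]]$w, b = cc$mods[[win]]$b,
           ref_icv = cc$pp$ref_icv, scaler = cc$pp$scaler, lambda = lambda)
    })
  }
  list(members = members, lambda = lambda,
       inner_bac = stats::setNames(mean_bac, grid))
}

.score_members <- function(members, Xraw, icv, idx) {
  s <- vapply(members, function(m) {
    pp <- list(ref_icv = m$ref_icv, scaler = m$scaler)
    Z <- .apply_preproc(pp, Xraw, icv, idx)
    as.numeric(Z %*% m$w + m$b)
  }, numeric(length(idx)))
  if (length(idx) == 1L) s <- matrix(s, nrow = 1L)
  rowMeans(s)
}

#' Fit a leave-site-out linear classifier ensemble
#'
#' The central estimator: trains a regularized linear classifier (L2 logistic
#' regression by default, or a linear hinge-loss SVM) to predict a binary
#' 9-month outcome under nested cross-validation with leave-site-out outer
#' folds. For each outer fold the inner repeated stratified CV selects the
#' regularization strength maximizing mean inner balanced accuracy; all inner
#' models at the winning value are retained as ensemble members, and each
#' held-out site's subjects are scored by the mean member decision score
#' (threshold 0 gives predicted labels). Every subject thus receives exactly
#' one out-of-site decision score. Preprocessing (reference-ICV normalization
#' for the gyrification view, z-standardization) is estimated strictly inside
#' each member's training partition.
#'
#' Class imbalance is handled by inverse-prevalence sample weights
#' (`balance = TRUE`, the default).
#'
#' @param cohort A `cohort_table`.
#' @param outcome `"negsym"` (moderate/severe negative symptoms, the default),
#'   `"gf_social"` or `"gf_role"` (impaired functioning), or a numeric 0/1
#'   vector aligned with the cohort rows.
#' @param view `"sips_n"` (5 baseline items) or `"gyrification"` (68 ROIs).
#' @param loss `"logistic"` or `"hinge"`.
#' @param grid Regularization strengths (lambda); for the hinge loss the SVM
#'   cost is `1/lambda`.
#' @param inner_k,inner_r Inner CV folds and repeats.
#' @param seed Seed for the fold assignments.
#' @param balance Inverse-prevalence sample weighting.
#' @param scale_items Z-standardize features (always on for gyrification; for
#'   the ordinal SIPS items it may be disabled).
#' @param ensemble `"average"` (retain all inner models at the winning
#'   hyperparameter; default) or `"refit"` (one refit per outer fold on the
#'   full outer training set).
#' @param scheme Optionally a precomputed [make_lso_scheme()] (must match the
#'   cohort and labels).
#' @return Object of class `lso_fit` with components `scores` (out-of-site
#'   decision scores per subject), `folds` (per-site ensembles), `y`,
#'   `feature_names`, and the settings. Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_site = 30, seed = 3))
#' fit <- fit_lso(cohort, view = "sips_n", inner_r = 2, seed = 3)
#' summary(fit)
#' @export
fit_lso <- function(cohort, outcome = "negsym",
                    view = c("sips_n", "gyrification"),
                    loss = c("logistic", "hinge"),
                    grid = 10^seq(3, -3, length.out = 7),
                    inner_k = 5L, inner_r = 10L, seed = 1L,
                    balance = TRUE, scale_items = TRUE,
                    ensemble = c("average", "refit"), scheme = NULL) {
  view <- match.arg(view)
  loss <- match.arg(loss)
  ensemble <- match.arg(ensemble)
  if (!length(grid)) stop("hyperparameter grid must be non-empty")
  y <- .resolve_outcome(cohort, outcome)
  fm <- feature_matrix(cohort, view)
  if (is.null(scheme)) {
    scheme <- make_lso_scheme(cohort, y, inner_k = inner_k, inner_r = inner_r,
                              seed = seed)
  }
  use_icv <- view == "gyrification"
  scale_features <- if (view == "sips_n") scale_items else TRUE

  folds <- vector("list", length(scheme$outer))
  scores <- data.frame(subject_id = fm$subject_ids, site = as.character(cohort$site_id),
                       score = NA_real_, pred = NA_integer_, y = y,
                       fold = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(scheme$outer)) {
    of <- scheme$outer[[i]]
    tr <- of$train_idx
    res <- .train_one_outer(fm$X[tr, , drop = FALSE],
                            if (use_icv) fm$icv[tr] else NULL,
                            y[tr], of$inner, grid, loss, balance,
                            use_icv, scale_features, ensemble)
    s <- .score_members(res$members, fm$X, fm$icv, of$test_idx)
    scores$score[of$test_idx] <- s
    scores$pred[of$test_idx] <- as.integer(s > 0)
    scores$fold[of$test_idx] <- of$site
    folds[[i]] <- list(site = of$site, members = res$members,
                       lambda = res$lambda, inner_bac = res$inner_bac,
                       n_train = length(tr), n_test = length(of$test_idx))
  }
  structure(list(call = match.call(), view = view, outcome = if (is.character(outcome)) outcome else "custom",
                 loss = loss, grid = sort(grid, decreasing = TRUE),
                 inner_k = scheme$inner_k, inner_r = scheme$inner_r,
                 seed = scheme$seed, scheme = scheme, folds = folds,
                 scores = scores, y = y, feature_names = fm$feature_names,
                 train_ids = fm$subject_ids, balance = balance,
                 ensemble = ensemble),
            class = "lso_fit")
}

.resolve_outcome <- function(cohort, outcome) {
  if (is.character(outcome) && length(outcome) == 1L) {
    switch(outcome,
           negsym = label_negative_symptoms(cohort),
           gf_social = label_functioning(cohort$gf_social_t1),
           gf_role = label_functioning(cohort$gf_role_t1),
           stop("unknown outcome '", outcome, "'"))
  } else {
    y <- as.integer(outcome)
    if (length(y) != nrow(cohort) || !all(y %in% 0:1)) {
      stop("custom outcome must be a binary vector aligned with the cohort")
    }
    y
  }
}

#' Stack base models by training a meta-learner on out-of-site scores
#'
#' Combines two (or more) base models fitted with [fit_lso()] under the same
#' leave-site-out scheme. The meta-features are the base models' out-of-site
#' decision scores -- never in-sample scores, which is asserted via fold
#' provenance -- and the meta-learner is the same linear family trained under
#' the same nested scheme, yielding out-of-site stacked scores.
#'
#' @param base_fits List of `lso_fit` objects sharing cohort and scheme.
#' @param loss,grid,balance,ensemble As in [fit_lso()].
#' @return An `lso_fit` (view `"stacked"`).
#' @export
fit_stacked <- function(base_fits, loss = c("logistic", "hinge"),
                        grid = 10^seq(3, -3, length.out = 7),
                        balance = TRUE, ensemble = c("average", "refit")) {
  loss <- match.arg(loss)
  ensemble <- match.arg(ensemble)
  if (length(base_fits) < 2L) stop("stacking needs at least two base models")
  ids <- base_fits[[1]]$scores$subject_id
  y <- base_fits[[1]]$y
  scheme <- base_fits[[1]]$scheme
  for (f in base_fits) {
    if (!inherits(f, "lso_fit")) stop("base models must be lso_fit objects")
    if (!identical(f$scores$subject_id, ids) || !identical(f$y, y)) {
      stop("base models were not fitted on the same cohort")
    }
    if (!identical(f$scheme$sites, scheme$sites)) {
      stop("base models were not fitted under the same outer scheme")
    }
    if (anyNA(f$scores$score) || !identical(f$scores$fold, f$scores$site)) {
      stop("leakage: base model scores are not complete out-of-site scores")
    }
  }
  meta <- do.call(cbind, lapply(base_fits, function(f) f$scores$score))
  colnames(meta) <- vapply(base_fits, function(f) paste0("score_", f$view), "")

  folds <- vector("list", length(scheme$outer))
  scores <- base_fits[[1]]$scores
  scores$score <- NA_real_; scores$pred <- NA_integer_; scores$fold <- NA_character_
  for (i in seq_along(scheme$outer)) {
    of <- scheme$outer[[i]]
    res <- .train_one_outer(meta[of$train_idx, , drop = FALSE], NULL,
                            y[of$train_idx], of$inner, grid, loss, balance,
                            use_icv = FALSE, scale_features = TRUE, ensemble)
    s <- .score_members(res$members, meta, NULL, of$test_idx)
    scores$score[of$test_idx] <- s
    scores$pred[of$test_idx] <- as.integer(s > 0)
    scores$fold[of$test_idx] <- of$site
    folds[[i]] <- list(site = of$site, members = res$members,
                       lambda = res$lambda, inner_bac = res$inner_bac,
                       n_train = length(of$train_idx), n_test = length(of$test_idx))
  }
  structure(list(call = match.call(), view = "stacked",
                 outcome = base_fits[[1]]$outcome, loss = loss,
                 grid = sort(grid, decreasing = TRUE),
                 inner_k = scheme$inner_k, inner_r = scheme$inner_r,
                 seed = scheme$seed, scheme = scheme, folds = folds,
                 scores = scores, y = y,
                 feature_names = colnames(meta), train_ids = ids,
                 balance = balance, ensemble = ensemble,
                 base_views = vapply(base_fits, function(f) f$view, ""),
                 base_fits = base_fits),
            class = "lso_fit")
}

#' @export
print.lso_fit <- function(x, ...) {
  cat(sprintf("Leave-site-out %s model (%s view)\n",
              if (x$loss == "logistic") "logistic-regression" else "linear-SVM", x$view))
  cat(sprintf("  outcome: %s | %d sites | inner %d-fold x %d | %d ensemble members\n",
              x$outcome, length(x$folds), x$inner_k, x$inner_r,
              sum(vapply(x$folds, function(f) length(f$members), integer(1)))))
  pm <- point_metrics(confusion_counts(x$scores$pred, x$y))
  cat(sprintf("  out-of-site BAC %.3f (AUC %.3f)\n", pm$BAC,
              auc_mw(x$scores$score, x$y)))
  invisible(x)
}

#' Summarize out-of-site performance of a fitted model
#'
#' @param object An `lso_fit`.
#' @param prior,posterior_method Passed to [posterior_bac()].
#' @param ... Unused.
#' @return A [performance_report()] with a per-site breakdown attached.
#' @export
summary.lso_fit <- function(object, prior = c(1, 1),
                            posterior_method = "grid_convolution", ...) {
  rep <- performance_report(object$scores$score, object$y,
                            pred = object$scores$pred, prior = prior,
                            posterior_method = posterior_method)
  per_site <- do.call(rbind, lapply(split(object$scores, object$scores$site), function(d) {
    data.frame(site = d$site[1], n = nrow(d), positives = sum(d$y),
               accuracy = mean(d$pred == d$y), stringsAsFactors = FALSE)
  }))
  rownames(per_site) <- NULL
  rep$per_site <- per_site
  rep$view <- object$view
  rep
}

#' Pooled feature weights of a fitted ensemble
#'
#' Mean of the unit-Euclidean-normalized member weight vectors over all
#' retained ensemble members across outer folds (the numerator of the
#' cross-validation ratio; see [cvr_profile()]).
#'
#' @param object An `lso_fit`.
#' @param normalize Normalize each member's weight vector to unit L2 norm.
#' @param ... Unused.
#' @return Named numeric vector, one weight per feature.
#' @export
coef.lso_fit <- function(object, normalize = TRUE, ...) {
  W <- weight_matrix(object, normalize = normalize)
  stats::setNames(colMeans(W), object$feature_names)
}

#' Member-by-feature weight matrix of a fitted ensemble
#'
#' @param fit An `lso_fit`.
#' @param normalize Normalize each member row to unit L2 norm.
#' @return Numeric matrix, members x features.
#' @export
weight_matrix <- function(fit, normalize = TRUE) {
  rows <- lapply(fit$folds, function(f) {
    do.call(rbind, lapply(f$members, function(m) m$w))
  })
  W <- do.call(rbind, rows)
  colnames(W) <- fit$feature_names
  if (normalize) {
    nrm <- sqrt(rowSums(W^2))
    nrm[nrm == 0] <- 1
    W <- W / nrm
  }
  W
}

#' Score new subjects with the grand ensemble
#'
#' Applies the full set of retained members (all outer folds) to an external
#' cohort: each member uses its own stored preprocessing (reference ICV,
#' scaler), and the subject's decision score is the mean over members; labels
#' at threshold 0. Used for transdiagnostic generalization (e.g. models
#' trained on a CHR cohort applied to ROP/ROD cohorts) and for functional
#' outcomes. Scoring subjects that were part of the training cohort is refused
#' (set `guard = FALSE` for deliberate in-sample diagnostics).
#'
#' @param object An `lso_fit`.
#' @param newdata A `cohort_table` (or data.frame) with the required feature
#'   columns for the model's view; for stacked models, a list of the base
#'   models is embedded and applied first.
#' @param type `"score"`, `"label"`, or `"response"` (logistic probability).
#' @param guard Refuse subjects whose ids overlap the training cohort.
#' @param ... Unused.
#' @return Data frame with `subject_id`, `score`, `pred` (and `prob` for
#'   `type = "response"`).
#' @export
predict.lso_fit <- function(object, newdata, type = c("score", "label", "response"),
                            guard = TRUE, ...) {
  type <- match.arg(type)
  if (guard && any(newdata$subject_id %in% object$train_ids)) {
    stop("refusing to score subjects from the training cohort in evaluation mode ",
         "(set guard = FALSE for in-sample diagnostics)")
  }
  if (object$view == "stacked") {
    meta <- do.call(cbind, lapply(object$base_fits, function(f) {
      predict(f, newdata, guard = guard)$score
    }))
    X <- meta; icv <- NULL
  } else {
    fm <- feature_matrix(newdata, object$view)
    X <- fm$X; icv <- fm$icv
  }
  members <- do.call(c, lapply(object$folds, function(f) f$members))
  s <- .score_members(members, X, icv, seq_len(nrow(X)))
  out <- data.frame(subject_id = newdata$subject_id, score = s,
                    pred = as.integer(s > 0), stringsAsFactors = FALSE)
  if (type == "response") out$prob <- stats::plogis(s)
  if (type == "label") out$score <- NULL
  out
}

#' @export
residuals.lso_fit <- function(object, ...) {
  if (object$loss != "logistic") {
    stop("response residuals are defined for the logistic loss only")
  }
  object$y - stats::plogis(object$scores$score)
}

#' ROC curve of the out-of-site decision scores
#'
#' @param x An `lso_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lso_fit <- function(x, ...) {
  ord <- order(x$scores$score, decreasing = TRUE)
  yy <- x$y[ord]
  tpr <- c(0, cumsum(yy) / sum(yy))
  fpr <- c(0, cumsum(1 - yy) / sum(1 - yy))
  graphics::plot(fpr, tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC (%s view), AUC = %.3f", x$view,
                                auc_mw(x$scores$score, x$y)), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
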