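#' Leave-site-out nested cross-validation scheme
#'
#' Builds the cross-validation plan used throughout: one outer fold per
#' recruitment site (each site serves exactly once as the held-out test set,
#' probing geographic generalizability to an unseen centre), and, within each
#' outer training set, `inner_k`-fold cross-validation stratified by outcome
#' label and repeated `inner_r` times for hyperparameter selection.
#'
#' @param cohort A `cohort_table` (only `site_id` and the outcome are used).
#' @param y Binary outcome labels, one per row; defaults to
#'   [label_negative_symptoms()] applied to the cohort.
#' @param inner_k Inner folds (default 5).
#' @param inner_r Inner repeats (default 10).
#' @param seed Seed controlling the inner fold assignments.
#' @return Object of class `cv_scheme`: `sites`, and per outer fold the test
#'   site, train/test row indices and an `n_train x inner_r` matrix of inner
#'   fold ids.
#' @export
make_lso_scheme <- function(cohort, y = label_negative_symptoms(cohort),
                            inner_k = 5L, inner_r = 10L, seed = 1L) {
  site <- as.factor(cohort$site_id)
  sites <- levels(droplevels(site))
  if (length(sites) < 2L) stop("leave-site-out CV needs at least 2 sites")
  if (inner_k < 1L || inner_r < 1L) stop("inner_k and inner_r must be >= 1")
  y <- as.integer(y)
  if (length(y) != nrow(cohort)) stop("labels must align with cohort rows")

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({ if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) })
  set.seed(seed)

  outer <- lapply(sites, function(s) {
    test_idx <- which(site == s)
    train_idx <- which(site != s)
    ytr <- y[train_idx]
    if (length(unique(ytr)) < 2L) {
      stop("outer training set excluding site '", s, "' contains a single outcome class")
    }
    inner <- if (inner_k >= 2L) {
      vapply(seq_len(inner_r), function(r) {
        .stratified_folds(ytr, inner_k)
      }, integer(length(train_idx)))
    } else {
      matrix(1L, length(train_idx), inner_r)
    }
    list(site = s, test_idx = test_idx, train_idx = train_idx, inner = inner)
  })
  structure(list(sites = sites, outer = outer, inner_k = as.integer(inner_k),
                 inner_r = as.integer(inner_r), seed = as.integer(seed)),
            class = "cv_scheme")
}

# Stratified k-fold assignment; re-drawn if any fold's complement (the inner
# training set) would contain a single class.
.stratified_folds <- function(y, k, max_tries = 100L) {
  n <- length(y)
  for (try in seq_len(max_tries)) {
    fold <- integer(n)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(y[fold != f])) == 2L
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not draw inner folds with both classes in every training set")
}

#' @export
print.cv_scheme <- function(x, ...) {
  cat(sprintf("Leave-site-out CV scheme: %d outer folds (sites: %s)\n",
              length(x$sites), paste(x$sites, collapse = ", ")))
  cat(sprintf("  inner loop: %d-fold x %d repeats, stratified by outcome (seed %d)\n",
              x$inner_k, x$inner_r, x$seed))
  invisible(x)
}
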