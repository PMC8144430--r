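#' A binary diagnostic test summarized by sensitivity and specificity
#'
#' @param name Test label (e.g. `"SIPS-N"`, `"gyrification"`).
#' @param sensitivity,specificity Proportions strictly in (0, 1).
#' @return Object of class `diagnostic_test`.
#' @export
diagnostic_test <- function(name, sensitivity, specificity) {
  for (v in c(sensitivity, specificity)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop("sensitivity and specificity must lie strictly in (0, 1)")
    }
  }
  structure(list(name = as.character(name), sensitivity = sensitivity,
                 specificity = specificity),
            class = "diagnostic_test")
}

#' Bayesian posttest probability after one test result
#'
#' Updates the probability of the bad outcome by Bayes' rule through a test's
#' sensitivity (SE) and specificity (SP): a positive result gives
#' `p.SE / (p.SE + (1-p)(1-SP))` (the test's PPV at pretest `p`), a negative
#' result gives `p(1-SE) / (p(1-SE) + (1-p).SP)`. An uninformative test
#' (SE + SP = 1, likelihood ratio 1) leaves the probability unchanged.
#'
#' @param p Pretest probability in (0, 1); the degenerate values 0/1 are
#'   returned unchanged with a warning.
#' @param test A [diagnostic_test()].
#' @param result `"+"` or `"-"` (also accepts `TRUE`/`FALSE`).
#' @return Posttest probability.
#' @examples
#' t1 <- diagnostic_test("SIPS-N", 0.47, 0.89)
#' posttest_probability(0.40, t1, "+")  # 0.7402
#' posttest_probability(0.40, t1, "-")  # 0.2842
#' @export
posttest_probability <- function(p, test, result) {
  if (!inherits(test, "diagnostic_test")) stop("'test' must be a diagnostic_test")
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
    stop("pretest probability must lie in [0, 1]")
  }
  if (p == 0 || p == 1) {
    warning("degenerate pretest probability ", p, " returned unchanged")
    return(p)
  }
  pos <- if (is.logical(result)) result else {
    if (!result %in% c("+", "-")) stop("result must be '+' or '-'")
    result == "+"
  }
  se <- test$sensitivity; sp <- test$specificity
  if (pos) p * se / (p * se + (1 - p) * (1 - sp))
  else     p * (1 - se) / (p * (1 - se) + (1 - p) * sp)
}

#' Risk category from a posttest probability
#'
#' High risk above 80\%, medium risk within 40--64\%, low risk below 20\%;
#' probabilities falling in the uncovered gaps (20--40\%, 64--80\%) are
#' labelled `"indeterminate"` rather than silently absorbed into a bin.
#'
#' @param p Probability in \[0, 1\] (vectorized).
#' @return Character vector in `{"high", "medium", "low", "indeterminate"}`.
#' @export
assign_risk_category <- function(p) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  ifelse(p > 0.80, "high",
         ifelse(p >= 0.40 & p <= 0.64, "medium",
                ifelse(p < 0.20, "low", "indeterminate")))
}

#' Number needed to treat from a posttest probability and intervention risk ratio
#'
#' Absolute risk reduction ARR = posttest probability x (1 - RR), where RR is
#' the intervention's risk ratio (RR < 1 means benefit); NNT = 1/ARR, reported
#' as the exact real value together with its nearest-integer rounding.
#'
#' @param posttest_p Probability of the bad outcome without intervention, in
#'   (0, 1\].
#' @param rr Risk ratio of the intervention, strictly in (0, 1).
#' @return List with `arr`, `nnt` (exact), `nnt_rounded`.
#' @examples
#' nnt(0.5, 0.5)  # ARR 0.25, NNT 4
#' @export
nnt <- function(posttest_p, rr) {
  if (!is.numeric(rr) || length(rr) != 1L || rr <= 0) stop("risk ratio must be positive")
  if (rr >= 1) stop("risk ratio >= 1 implies no treatment benefit; NNT undefined")
  if (!is.numeric(posttest_p) || posttest_p <= 0 || posttest_p > 1) {
    stop("posttest probability must lie in (0, 1]")
  }
  arr <- posttest_p * (1 - rr)
  list(arr = arr, nnt = 1 / arr, nnt_rounded = as.integer(round(1 / arr)))
}

#' Build a sequential Bayesian risk-stratification tree
#'
#' Simulates a staged assessment in which tests are administered in order
#' (e.g. a clinical SIPS-N rating first, then a gyrification signature from
#' structural MRI) and the outcome probability is updated after each result by
#' [posttest_probability()]. Every result path is enumerated: each node
#' carries the chained posttest probability, the path's marginal probability
#' mass under the pretest prevalence (law of total probability), its risk
#' category and, if a risk ratio is supplied, the NNT for an intervention.
#'
#' @param pretest Pretest probability (base rate) in (0, 1).
#' @param tests List of [diagnostic_test()]s, administered in order.
#' @param rr Optional intervention risk ratio in (0, 1) for NNT annotation.
#' @return Object of class `strat_tree` with `nodes` (data.frame over all
#'   2^(depth+1) - 1 nodes: `path`, `depth`, `posttest_p`, `branch_mass`,
#'   `category`, `nnt`, `nnt_rounded`), `leaves` (the terminal rows),
#'   `pretest`, `tests`, `rr`.
#' @examples
#' tree <- build_stratification_tree(
#'   0.40,
#'   list(diagnostic_test("SIPS-N", 0.47, 0.89),
#'        diagnostic_test("gyrification", 0.61, 0.64)),
#'   rr = 0.8)
#' round(100 * tree$leaves$posttest_p)  # 83 63 40 19 (paths ++, +-, -+, --)
#' @export
build_stratification_tree <- function(pretest, tests, rr = NULL) {
  if (!length(tests)) stop("at least one diagnostic test is required")
  if (!is.numeric(pretest) || pretest <= 0 || pretest >= 1) {
    stop("pretest probability must lie strictly in (0, 1)")
  }
  tests <- lapply(tests, function(t) {
    if (!inherits(t, "diagnostic_test")) do.call(diagnostic_test, as.list(t)) else t
  })
  depth <- length(tests)

  nodes <- list()
  # walk(path_string, current posttest p, current path mass, level)
  walk <- function(path, p, mass, level) {
    nodes[[length(nodes) + 1L]] <<- data.frame(
      path = path, depth = level, posttest_p = p, branch_mass = mass,
      stringsAsFactors = FALSE)
    if (level == depth) return(invisible())
    t <- tests[[level + 1L]]
    # P(+ | current branch): mixture over disease status within the branch
    p_pos <- p * t$sensitivity + (1 - p) * (1 - t$specificity)
    walk(paste0(path, "+"), posttest_probability(p, t, "+"), mass * p_pos, level + 1L)
    walk(paste0(path, "-"), posttest_probability(p, t, "-"), mass * (1 - p_pos), level + 1L)
  }
  walk("", pretest, 1, 0L)
  nodes <- do.call(rbind, nodes)
  nodes$category <- assign_risk_category(nodes$posttest_p)
  if (!is.null(rr)) {
    nn <- lapply(nodes$posttest_p, nnt, rr = rr)
    nodes$nnt <- vapply(nn, `[[`, numeric(1), "nnt")
    nodes$nnt_rounded <- vapply(nn, `[[`, integer(1), "nnt_rounded")
  }
  leaves <- nodes[nodes$depth == depth, , drop = FALSE]
  leaves <- leaves[order(.path_key(leaves$path), decreasing = TRUE), , drop = FALSE]  # ++, +-, -+, --
  rownames(leaves) <- NULL
  structure(list(pretest = pretest, tests = tests, rr = rr,
                 nodes = nodes, leaves = leaves, depth = depth),
            class = "strat_tree")
}

# locale-independent ordering of result paths: read "+"/"-" as binary digits,
# so "++" > "+-" > "-+" > "--" regardless of collation
.path_key <- function(path) {
  vapply(strsplit(path, ""), function(ch) sum((ch == "+") * 2^(rev(seq_along(ch)) - 1)),
         numeric(1))
}

#' @export
print.strat_tree <- function(x, ...) {
  cat(sprintf("Sequential risk stratification: pretest %.1f%%, tests: %s\n",
              100 * x$pretest,
              paste(vapply(x$tests, function(t) {
                sprintf("%s (SE %.2f, SP %.2f)", t$name, t$sensitivity, t$specificity)
              }, ""), collapse = " -> ")))
  l <- x$leaves
  for (i in seq_len(nrow(l))) {
    cat(sprintf("  path %-4s posttest %5.1f%%  mass %5.1f%%  %-13s%s\n",
                l$path[i], 100 * l$posttest_p[i], 100 * l$branch_mass[i],
                l$category[i],
                if (!is.null(x$rr)) sprintf("  NNT %.1f (~%d)", l$nnt[i], l$nnt_rounded[i]) else ""))
  }
  invisible(x)
}

#' Probabilistic-assessment diagram of a stratification tree
#'
#' Plots posttest probability against assessment stage, with solid ascending
#' segments for positive results and dashed descending segments for negative
#' results; point size reflects branch mass.
#'
#' @param x A `strat_tree`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.strat_tree <- function(x, ...) {
  nd <- x$nodes
  graphics::plot(NA, xlim = c(0, x$depth), ylim = c(0, 1),
                 xlab = "Sequential tests", ylab = "PPV (posttest probability)",
                 xaxt = "n", main = "Two-stage probabilistic assessment", ...)
  graphics::axis(1, at = 0:x$depth,
                 labels = c("pretest", vapply(x$tests, `[[`, "", "name")))
  for (i in which(nd$depth > 0)) {
    parent <- substr(nd$path[i], 1L, nchar(nd$path[i]) - 1L)
    j <- which(nd$path == parent & nd$depth == nd$depth[i] - 1L)
    pos <- substring(nd$path[i], nchar(nd$path[i])) == "+"
    graphics::segments(nd$depth[j], nd$posttest_p[j], nd$depth[i], nd$posttest_p[i],
                       lty = if (pos) 1 else 2)
  }
  graphics::points(nd$depth, nd$posttest_p, pch = 16,
                   cex = 0.5 + 2.5 * nd$branch_mass)
  graphics::abline(h = c(0.2, 0.4, 0.64, 0.8), col = "grey80", lty = 3)
  invisible(x)
}

#' Observed outcome rates along each test-result path
#'
#' The empirical analogue of the tree's theoretical posttest probabilities:
#' for every result path over the supplied binary test-result columns, the
#' observed outcome rate and subject count in the cohort. Paths with no
#' subjects are flagged with an `NA` rate rather than divided by zero.
#'
#' @param data Data frame holding the test-result columns and the outcome.
#' @param test_cols Character vector of binary (0/1) test-result columns, in
#'   administration order.
#' @param outcome_col Name of the binary outcome column.
#' @return Data frame: `path`, `n`, `n_bad`, `rate`, `empty`.
#' @export
empirical_branch_rates <- function(data, test_cols, outcome_col = "negsym_bad") {
  missing_cols <- setdiff(c(test_cols, outcome_col), names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  res <- lapply(test_cols, function(cl) {
    v <- data[[cl]]
    if (!all(v %in% 0:1)) stop("test column '", cl, "' must be binary 0/1")
    v
  })
  y <- data[[outcome_col]]
  depth <- length(test_cols)
  paths <- do.call(expand.grid, rep(list(c("+", "-")), depth))[, depth:1, drop = FALSE]
  path_str <- apply(paths, 1L, paste0, collapse = "")
  out <- do.call(rbind, lapply(path_str, function(ps) {
    sel <- rep(TRUE, nrow(data))
    for (d in seq_len(depth)) {
      sel <- sel & (res[[d]] == as.integer(substring(ps, d, d) == "+"))
    }
    data.frame(path = ps, n = sum(sel), n_bad = sum(y[sel]),
               rate = if (any(sel)) mean(y[sel]) else NA_real_,
               empty = !any(sel), stringsAsFactors = FALSE)
  }))
  out <- out[order(.path_key(out$path), decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
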