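test_that("point metrics reproduce hand arithmetic on reconstructed counts", {
  m <- point_metrics(list(TP = 18, FP = 6, TN = 50, FN = 20))
  expect_equal(m$SE, 18 / 38)
  expect_equal(m$SP, 50 / 56)
  expect_equal(m$PPV, 18 / 24)
  expect_equal(m$NPV, 50 / 70)
  expect_equal(m$BAC, (18 / 38 + 50 / 56) / 2)
  expect_equal(round(100 * c(m$SE, m$SP, m$PPV, m$NPV)), c(47, 89, 75, 71))
})

test_that("degenerate classifiers are handled explicitly", {
  perfect <- point_metrics(list(TP = 10, FP = 0, TN = 12, FN = 0))
  expect_equal(c(perfect$SE, perfect$SP, perfect$BAC), c(1, 1, 1))
  allpos <- point_metrics(list(TP = 10, FP = 12, TN = 0, FN = 0))
  expect_equal(c(allpos$SE, allpos$SP, allpos$BAC), c(1, 0, 0.5))
  expect_true(is.na(allpos$NPV))
  expect_equal(allpos$undefined, "NPV")
  expect_error(point_metrics(list(TP = 0, FP = 5, TN = 5, FN = 0)), "positive class")
})

test_that("BAC identity holds for random confusion counts", {
  set.seed(7)
  for (i in 1:25) {
    k <- as.list(stats::setNames(1 + stats::rpois(4, 20), c("TP", "FP", "TN", "FN")))
    m <- point_metrics(k)
    expect_identical(m$BAC, (m$SE + m$SP) / 2)
  }
})

test_that("AUC matches brute-force pair enumeration", {
  expect_equal(auc_mw(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_mw(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_equal(auc_mw(rep(1, 10), rep(0:1, 5)), 0.5)
  expect_error(auc_mw(1:4, c(1, 1, 1, 1)), "both outcome classes")
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(stats::rnorm(n), 1)  # coarse scores force ties
    expect_equal(auc_mw(s, y), brute(s, y))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- sample(0:1, 80, replace = TRUE, prob = c(0.6, 0.4))
  s <- stats::rnorm(80) + y
  expect_equal(auc_mw(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("posterior BAC is symmetric, concentrates, and validates its prior", {
  sym <- posterior_bac(list(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(sym$mean, 0.5, tolerance = 1e-10)
  lim <- posterior_bac(list(TP = 1000, FP = 0, TN = 1000, FN = 0))
  expect_gt(lim$mass_above_0.5, 0.999)
  expect_true(lim$significant)
  expect_error(posterior_bac(list(TP = 1, FP = 1, TN = 1, FN = 1),
                             prior = c(-1, 1)), "prior")
})

test_that("grid convolution and Monte Carlo posteriors agree", {
  counts <- list(TP = 18, FP = 6, TN = 50, FN = 20)
  g <- posterior_bac(counts, method = "grid_convolution")
  mc <- posterior_bac(counts, method = "monte_carlo", n_draws = 1e6, seed = 2)
  expect_equal(g$mean, mc$mean, tolerance = 0.005 / g$mean)
  expect_lt(max(abs(g$ci - mc$ci)), 0.005)
  expect_equal(g$mass_above_0.5, mc$mass_above_0.5, tolerance = 0.01)
})

test_that("posterior concentrates on the point BAC as counts scale up", {
  base <- c(TP = 18, FP = 6, TN = 50, FN = 20)
  point <- point_metrics(as.list(base))$BAC
  widths <- means <- numeric(3)
  for (i in seq_along(c(1, 10, 100))) {
    f <- c(1, 10, 100)[i]
    p <- posterior_bac(as.list(base * f))
    widths[i] <- diff(p$ci)
    means[i] <- p$mean
  }
  expect_true(all(diff(widths) < 0))
  expect_equal(means[3], point, tolerance = 0.005 / point)
})

test_that("the significance criterion is calibrated under the null", {
  set.seed(33)
  fired <- logical(400)
  for (i in seq_along(fired)) {
    tp <- stats::rbinom(1, 50, 0.5); tn <- stats::rbinom(1, 50, 0.5)
    fired[i] <- posterior_bac(list(TP = tp, FN = 50 - tp,
                                   TN = tn, FP = 50 - tn))$significant
  }
  expect_lte(mean(fired), 0.10)
})

test_that("performance_report assembles counts, AUC and posterior coherently", {
  set.seed(5)
  y <- sample(0:1, 60, replace = TRUE)
  s <- stats::rnorm(60) + 1.2 * y - 0.6
  rep <- performance_report(s, y)
  expect_equal(rep$metrics$BAC, (rep$metrics$SE + rep$metrics$SP) / 2)
  expect_equal(rep$counts$TP + rep$counts$FN, sum(y))
  expect_equal(rep$auc, auc_mw(s, y))
  expect_output(print(rep), "Performance")
})
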