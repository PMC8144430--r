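test_that("generation is deterministic given the config", {
  cfg <- cohort_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(attr(a, "meta")$signal_rois, attr(b, "meta")$signal_rois)
  c2 <- generate_cohort(cohort_config(seed = 12))
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("cohort table honours the schema invariants", {
  cohort <- small_cohort(seed = 5)
  expect_s3_class(cohort, "cohort_table")
  expect_equal(nrow(cohort), 7 * 30)
  expect_true(all(roi_names() %in% names(cohort)))
  expect_length(roi_names(), 68)
  items <- as.matrix(cohort[, grep("^sips_", names(cohort))])
  expect_true(all(items >= 0 & items <= 6))
  expect_true(all(cohort$gf_social_t1 >= 1 & cohort$gf_social_t1 <= 10))
  expect_true(all(cohort$icv > 0))
  expect_equal(nlevels(cohort$site_id), 7)
  expect_false(anyNA(cohort))
})

test_that("invalid config fields raise errors naming the field", {
  expect_error(cohort_config(target_prevalence = 1.2), "target_prevalence")
  expect_error(cohort_config(target_prevalence = 0), "target_prevalence")
  expect_error(cohort_config(n_signal_rois = 99), "n_signal_rois")
  expect_error(cohort_config(site_sd = -1), "site_sd")
  expect_error(cohort_config(n_per_site = c(10, 10)), "n_per_site")
  expect_error(cohort_config(clinical_effect = 1.5), "clinical_effect")
})

test_that("realized prevalence converges to the target", {
  big <- generate_cohort(cohort_config(n_per_site = 1343, seed = 2))  # n = 9401
  expect_equal(mean(label_negative_symptoms(big)),
               0.40, tolerance = 0.02 / 0.40)
  null2k <- generate_null_cohort(cohort_config(n_per_site = 286,
                                               target_prevalence = 0.5, seed = 8))
  expect_equal(mean(label_negative_symptoms(null2k)), 0.5, tolerance = 0.03 / 0.5)
  rop <- generate_cohort(cohort_config(group = "ROP", n_per_site = 300, seed = 4))
  expect_equal(mean(label_negative_symptoms(rop)), 0.59, tolerance = 0.03 / 0.59)
})

test_that("null cohorts carry no feature-outcome association", {
  cohort <- generate_null_cohort(cohort_config(n_per_site = 286, seed = 13))
  y <- label_negative_symptoms(cohort)
  feats <- c("sips_n1_t0", "sips_n2_t0", "sips_n3_t0", "sips_n4_t0",
             "sips_n6_t0", sample(roi_names(), 10))
  for (f in feats) {
    expect_lt(abs(stats::cor(as.numeric(cohort[[f]]), y)), 0.08)
  }
})

test_that("planted ROI signal magnitude and sign are recovered", {
  cohort <- generate_cohort(cohort_config(n_per_site = 286, roi_effect = 0.8,
                                          n_signal_rois = 8, seed = 21))
  meta <- attr(cohort, "meta")
  y <- label_negative_symptoms(cohort)
  expect_length(meta$signal_rois, 8)
  for (k in seq_along(meta$signal_rois)) {
    d <- pooled_smd(underlying_roi(cohort, meta$signal_rois[k]), y)
    expect_equal(d, meta$signal_signs[k] * 0.8, tolerance = 0.15 / 0.8)
  }
  # non-signal ROIs: SMDs are pure sampling noise (SE ~ 0.046 at this n), so
  # judge the ensemble, not each draw: bulk within 0.1, none beyond ~3 SE
  non_signal <- setdiff(roi_names(), meta$signal_rois)
  d0 <- vapply(non_signal, function(r) {
    abs(pooled_smd(underlying_roi(cohort, r), y))
  }, numeric(1))
  expect_gte(mean(d0 < 0.1), 0.9)
  expect_lt(max(d0), 0.15)
  expect_lt(stats::median(d0), 0.05)
})

test_that("between-site variance of ROI means matches site_sd^2", {
  site_sd <- 0.1
  cohort <- generate_cohort(cohort_config(n_sites = 40, n_per_site = 50,
                                          site_sd = site_sd, n_signal_rois = 0,
                                          seed = 6))
  # one-way ANOVA estimator of the site-offset variance, averaged over ROIs
  est <- vapply(roi_names(), function(r) {
    v <- underlying_roi(cohort, r)
    m <- tapply(v, cohort$site_id, mean)
    msb <- 50 * stats::var(m)
    msw <- mean(tapply(v, cohort$site_id, stats::var))
    (msb - msw) / 50
  }, numeric(1))
  expect_equal(mean(est), site_sd^2, tolerance = 0.25)
})

test_that("null generator keeps marginals but zeroes the effects", {
  cfg <- cohort_config(seed = 31, n_per_site = 100)
  nullc <- generate_null_cohort(cfg)
  meta <- attr(nullc, "meta")
  expect_equal(meta$config$clinical_effect, 0)
  expect_equal(meta$config$roi_effect, 0)
  # site offsets retained: between-site spread well above zero
  m <- tapply(underlying_roi(nullc, roi_names()[1]), nullc$site_id, mean)
  expect_gt(stats::var(m), 0)
})
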