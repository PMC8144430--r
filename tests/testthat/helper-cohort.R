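# Small cohorts reused across tests. All generation is seed-deterministic.

small_cohort <- function(seed = 3, n_per_site = 30, ...) {
  generate_cohort(cohort_config(n_per_site = n_per_site, seed = seed, ...))
}

# corrected ROI values with the head-size factor divided out, for checks on
# the generator's planted structure
underlying_roi <- function(cohort, roi) {
  cohort[[roi]] * 1.5e6 / cohort$icv
}

pooled_smd <- function(v, y) {
  s <- sqrt(((sum(y == 1) - 1) * stats::var(v[y == 1]) +
             (sum(y == 0) - 1) * stats::var(v[y == 0])) / (length(v) - 2))
  (mean(v[y == 1]) - mean(v[y == 0])) / s
}
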