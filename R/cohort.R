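# Desikan-Killiany surface atlas: 34 regions per hemisphere.
dk_regions <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate", "rostralmiddlefrontal",
  "superiorfrontal", "superiorparietal", "superiortemporal", "supramarginal",
  "temporalpole", "transversetemporal")

#' Names of the 68 gyrification ROI columns
#'
#' Left/right hemisphere times the 34 Desikan-Killiany atlas regions, in the
#' column order used by [generate_cohort()] and expected by [read_cohort()].
#'
#' @return Character vector of length 68.
#' @export
roi_names <- function() {
  c(paste0("gyr_lh_", dk_regions), paste0("gyr_rh_", dk_regions))
}

sips_t0_cols <- c("sips_n1_t0", "sips_n2_t0", "sips_n3_t0", "sips_n4_t0", "sips_n6_t0")
sips_t1_cols <- c("sips_n1_t1", "sips_n2_t1", "sips_n3_t1", "sips_n4_t1", "sips_n6_t1")

#' Configuration for the synthetic multi-site cohort generator
#'
#' Defines the statistical structure of a simulated clinical high-risk (CHR),
#' recent-onset psychosis (ROP) or recent-onset depression (ROD) cohort:
#' number of recruitment sites, per-site sample sizes, the follow-up prevalence
#' of the moderate/severe negative-symptom outcome, and the strength with which
#' baseline clinical severity and a planted subset of gyrification ROIs carry
#' outcome signal.
#'
#' @param n_sites Number of recruitment sites (default 7, the multi-site design
#'   the pipeline is built for).
#' @param n_per_site Integer vector of per-site sample sizes; a scalar is
#'   recycled across sites. The default reproduces a 94-subject CHR cohort.
#' @param group One of `"CHR"`, `"ROP"`, `"ROD"`.
#' @param target_prevalence Probability of a moderate/severe negative-symptom
#'   outcome at follow-up (defaults: CHR 0.40, ROP 0.59, ROD 0.32).
#' @param clinical_effect Standardized effect linking the baseline latent
#'   symptom severity to the follow-up severity driving the outcome
#'   (correlation scale, in \[0, 1)).
#' @param n_signal_rois Number of gyrification ROIs carrying outcome signal.
#' @param roi_effect Standardized between-class mean shift (Cohen's d, in units
#'   of the within-class ROI noise SD) of each signal ROI; per-ROI signs are
#'   drawn by the generator (80\% "reduced in bad outcome", i.e. negative).
#' @param site_sd SD of additive per-site, per-ROI offsets (same units as the
#'   ROI values), emulating scanner/site batch effects.
#' @param seed Integer random seed; the generator is fully deterministic given
#'   the configuration.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [generate_null_cohort()]
#' @export
cohort_config <- function(n_sites = 7L,
                          n_per_site = c(14L, 14L, 14L, 13L, 13L, 13L, 13L),
                          group = c("CHR", "ROP", "ROD"),
                          target_prevalence = NULL,
                          clinical_effect = 0.5,
                          n_signal_rois = 8L,
                          roi_effect = 0.8,
                          site_sd = 0.05,
                          seed = 1L) {
  group <- match.arg(group)
  if (is.null(target_prevalence)) {
    target_prevalence <- switch(group, CHR = 0.40, ROP = 0.59, ROD = 0.32)
  }
  if (length(n_sites) != 1L || !is.finite(n_sites) || n_sites < 1 ||
      n_sites != round(n_sites)) {
    stop("invalid cohort config: 'n_sites' must be a positive integer")
  }
  n_sites <- as.integer(n_sites)
  if (length(n_per_site) == 1L) n_per_site <- rep(n_per_site, n_sites)
  if (length(n_per_site) != n_sites || any(!is.finite(n_per_site)) ||
      any(n_per_site < 1) || any(n_per_site != round(n_per_site))) {
    stop("invalid cohort config: 'n_per_site' must be positive integer counts, one per site")
  }
  if (!is.numeric(target_prevalence) || length(target_prevalence) != 1L ||
      target_prevalence <= 0 || target_prevalence >= 1) {
    stop("invalid cohort config: 'target_prevalence' must lie strictly in (0, 1)")
  }
  if (!is.numeric(clinical_effect) || clinical_effect < 0 || clinical_effect >= 1) {
    stop("invalid cohort config: 'clinical_effect' must lie in [0, 1)")
  }
  if (n_signal_rois < 0 || n_signal_rois > 68 || n_signal_rois != round(n_signal_rois)) {
    stop("invalid cohort config: 'n_signal_rois' must be an integer in 0..68")
  }
  if (!is.numeric(roi_effect) || !is.finite(roi_effect)) {
    stop("invalid cohort config: 'roi_effect' must be a finite number")
  }
  if (!is.numeric(site_sd) || site_sd < 0) {
    stop("invalid cohort config: 'site_sd' must be >= 0")
  }
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
    stop("invalid cohort config: 'seed' must be an integer")
  }
  structure(list(
    n_sites = n_sites, n_per_site = as.integer(n_per_site), group = group,
    target_prevalence = target_prevalence, clinical_effect = clinical_effect,
    n_signal_rois = as.integer(n_signal_rois), roi_effect = roi_effect,
    site_sd = site_sd, seed = as.integer(seed)
  ), class = "cohort_config")
}

# Generator constants: ordinal bin width, item noise SDs, ROI noise SD, ICV scale.
.gen <- list(
  item_width   = 0.8,   # width of one ordinal step on the latent scale
  tau0         = 0.8,   # baseline item noise SD around the latent severity
  tau1         = 0.6,   # follow-up item noise SD around the follow-up severity
  roi_sd       = 0.15,  # within-class ROI noise SD (gyrification index units)
  icv_mean     = 1.5e6, # mm^3
  icv_cv       = 0.08,
  baseline_shift = 1.8  # centres baseline items around mild severity
)

# Threshold theta on the follow-up latent-plus-noise scale such that
# P(max over the 5 items of y + tau1*e_j >= theta) = prev, with y ~ N(0,1).
# Deterministic numeric integration over the shared severity y.
.calibrate_outcome_threshold <- function(prev, tau = .gen$tau1, n_items = 5L) {
  ygrid <- seq(-8, 8, length.out = 3201L)
  wy <- stats::dnorm(ygrid)
  wy <- wy / sum(wy)
  f <- function(theta) {
    sum(wy * stats::pnorm((theta - ygrid) / tau)^n_items) - (1 - prev)
  }
  stats::uniroot(f, c(-6, 10), tol = 1e-10)$root
}

.bin_ordinal <- function(u, offset, width = .gen$item_width) {
  pmin(6L, pmax(0L, as.integer(floor((u - offset) / width))))
}

#' Generate a synthetic multi-site cohort
#'
#' Simulates subject-level data with the dependence structure the downstream
#' pipeline assumes: a standard-normal latent severity per subject drives
#' (a) the five baseline SIPS negative-symptom items (N1-N4, N6) through
#' thresholded noisy copies, (b) the follow-up items -- and hence the binary
#' moderate/severe outcome via the labelling rule -- with strength
#' `clinical_effect`, and (c) mean shifts of `n_signal_rois` gyrification ROIs
#' between outcome classes of magnitude `roi_effect`. Per-site additive offsets
#' with SD `site_sd` batch-shift all ROI columns, and raw gyrification values
#' scale proportionally with the subject's intracranial volume (ICV), which the
#' feature pipeline undoes by ICV normalization. Global Functioning
#' Social/Role follow-up scores derive from the same follow-up severity with
#' independent noise so functional-outcome generalization is testable.
#'
#' The follow-up item threshold is calibrated by numerical integration so that
#' the realized outcome prevalence converges to `target_prevalence` as n grows.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` of class `cohort_table`, one row per subject, with
#'   columns `subject_id`, `site_id`, `group`, baseline items
#'   `sips_n{1,2,3,4,6}_t0` and `sips_n5_t0`, follow-up items
#'   `sips_n{1,2,3,4,6}_t1`, the 68 `gyr_*` ROI columns (see [roi_names()]),
#'   `icv`, `gf_social_t1`, `gf_role_t1`. Generator metadata (planted signal
#'   ROI names and signs, calibrated threshold, the config) is attached as
#'   `attr(x, "meta")`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' table(labels <- label_negative_symptoms(cohort))
#' attr(cohort, "meta")$signal_rois
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)

  n <- sum(config$n_per_site)
  site_levels <- sprintf("site%02d", seq_len(config$n_sites))
  site_id <- factor(rep(site_levels, times = config$n_per_site), levels = site_levels)
  rois <- roi_names()

  # planted-signal ROIs: 80% of signs negative (reduced gyrification in the
  # bad-outcome class), matching the directionality the importance module reports
  signal_idx <- if (config$n_signal_rois > 0) {
    sort(sample.int(68L, config$n_signal_rois))
  } else integer(0)
  signal_sign <- if (config$n_signal_rois > 0) {
    ifelse(stats::runif(config$n_signal_rois) < 0.8, -1, 1)
  } else numeric(0)

  z <- stats::rnorm(n)                               # baseline latent severity
  b <- config$clinical_effect
  y <- b * z + sqrt(1 - b^2) * stats::rnorm(n)       # follow-up severity, Var 1

  # baseline ordinal items from z
  t0 <- sapply(1:5, function(j) {
    .bin_ordinal(z + .gen$tau0 * stats::rnorm(n), offset = -.gen$baseline_shift)
  })
  colnames(t0) <- sips_t0_cols
  n5_t0 <- .bin_ordinal(stats::rnorm(n), offset = -.gen$baseline_shift)

  # follow-up ordinal items from y, thresholded so that any item >= 3 has
  # probability target_prevalence
  theta <- .calibrate_outcome_threshold(config$target_prevalence)
  t1 <- sapply(1:5, function(j) {
    u <- y + .gen$tau1 * stats::rnorm(n)
    pmin(6L, pmax(0L, 3L + as.integer(floor((u - theta) / .gen$item_width))))
  })
  colnames(t1) <- sips_t1_cols
  bad <- as.integer(apply(t1, 1, max) >= 3L)

  # gyrification: per-region baseline level + site batch offset + noise + signal
  g0 <- rep(seq(1.8, 3.2, length.out = 34L), 2L)
  site_off <- matrix(stats::rnorm(config$n_sites * 68L, sd = config$site_sd),
                     nrow = config$n_sites)
  underlying <- matrix(g0, n, 68L, byrow = TRUE) +
    site_off[as.integer(site_id), , drop = FALSE] +
    matrix(stats::rnorm(n * 68L, sd = .gen$roi_sd), n, 68L)
  if (length(signal_idx)) {
    shift <- config$roi_effect * .gen$roi_sd
    for (k in seq_along(signal_idx)) {
      underlying[, signal_idx[k]] <-
        underlying[, signal_idx[k]] + signal_sign[k] * shift * bad
    }
  }
  icv <- stats::rlnorm(n, meanlog = log(.gen$icv_mean), sdlog = .gen$icv_cv)
  gyr <- underlying * (icv / .gen$icv_mean)   # raw values scale with head size
  colnames(gyr) <- rois

  gf_social <- pmin(10L, pmax(1L, as.integer(round(8 - y + stats::rnorm(n)))))
  gf_role   <- pmin(10L, pmax(1L, as.integer(round(8 - y + stats::rnorm(n)))))

  tab <- data.frame(
    subject_id = sprintf("%s_%04d", tolower(config$group), seq_len(n)),
    site_id = site_id, group = config$group,
    t0, sips_n5_t0 = n5_t0, t1,
    icv = icv, gf_social_t1 = gf_social, gf_role_t1 = gf_role,
    gyr, check.names = FALSE, stringsAsFactors = FALSE)
  class(tab) <- c("cohort_table", "data.frame")
  attr(tab, "meta") <- list(
    signal_rois = rois[signal_idx],
    signal_signs = signal_sign,
    outcome_threshold = theta,
    config = config)
  tab
}

#' Generate a null cohort with no feature-outcome association
#'
#' Identical marginal distributions to [generate_cohort()], but every
#' feature-outcome effect is forced to zero (`clinical_effect = 0`,
#' `roi_effect = 0`); site batch effects are retained. Used for calibration of
#' the significance machinery: any downstream classifier should perform at
#' chance on its output.
#'
#' @inheritParams generate_cohort
#' @return A `cohort_table`, as for [generate_cohort()].
#' @export
generate_null_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  config$clinical_effect <- 0
  config$roi_effect <- 0
  generate_cohort(config)
}
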