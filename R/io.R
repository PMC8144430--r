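.required_cols <- function() {
  c("subject_id", "site_id", "group", sips_t0_cols, "sips_n5_t0", sips_t1_cols,
    "icv", "gf_social_t1", "gf_role_t1", roi_names())
}

#' Read a cohort table from CSV/TSV
#'
#' Delimiter is inferred from the extension (`.csv` comma, `.tsv`/`.txt` tab).
#' The schema is validated: all required columns (including the 68 ROI
#' columns) must be present, numeric columns numeric and complete, and subject
#' ids unique; violations are reported with the offending column/ids. If a
#' metadata JSON written by [write_cohort()] sits next to the file it is
#' re-attached.
#'
#' @param path File path.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_cols(), names(tab))
  if (length(missing_cols)) {
    stop("cohort file is missing required column(s): ",
         paste(utils::head(missing_cols, 8L), collapse = ", "))
  }
  dup <- unique(tab$subject_id[duplicated(tab$subject_id)])
  if (length(dup)) {
    stop("duplicate subject_id(s): ", paste(utils::head(dup, 8L), collapse = ", "))
  }
  num_cols <- setdiff(.required_cols(), c("subject_id", "site_id", "group"))
  for (cl in num_cols) {
    v <- tab[[cl]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric or missing entries in column '", cl, "' (rows ",
           paste(utils::head(bad, 5L), collapse = ", "), ")")
    }
  }
  tab$site_id <- factor(tab$site_id)
  class(tab) <- c("cohort_table", "data.frame")
  meta_path <- paste0(sub("\\.(csv|tsv|txt)$", "", path, ignore.case = TRUE), ".meta.json")
  if (file.exists(meta_path)) {
    attr(tab, "meta") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  }
  tab
}

#' Write a cohort table (and its generator metadata) to disk
#'
#' Numeric values are written with 17 significant digits so a write/read
#' round trip reproduces them exactly. Generator metadata, when attached, is
#' written as `<stem>.meta.json` next to the table.
#'
#' @param cohort A `cohort_table`.
#' @param path Destination (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- as.data.frame(cohort)
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- formatC(out[[cl]], digits = 17, format = "g")
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  meta <- attr(cohort, "meta")
  if (!is.null(meta)) {
    meta_path <- paste0(sub("\\.(csv|tsv|txt)$", "", path, ignore.case = TRUE), ".meta.json")
    meta$config <- unclass(meta$config)
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

.report_to_list <- function(rep) {
  m <- rep$metrics
  list(n = rep$n,
       counts = unclass(rep$counts)[c("TP", "FP", "TN", "FN")],
       BAC = m$BAC, AUC = rep$auc, SE = m$SE, SP = m$SP, PPV = m$PPV, NPV = m$NPV,
       percent = lapply(list(BAC = m$BAC, AUC = rep$auc, SE = m$SE, SP = m$SP,
                             PPV = m$PPV, NPV = m$NPV),
                        function(v) if (is.na(v)) NA else round(100 * v)),
       posterior = list(mean = rep$posterior$mean,
                        ci = rep$posterior$ci,
                        mass_above_0.5 = rep$posterior$mass_above_0.5,
                        significant = rep$posterior$significant))
}

#' Run the full prognostic analysis end-to-end
#'
#' Orchestrates the whole pipeline on one cohort: (optional) simulation,
#' outcome labelling, leave-site-out training of the SIPS-N and gyrification
#' models, stacking, performance evaluation of all three models (point
#' metrics, AUC, posterior balanced accuracy), CVR importance profiles of the
#' two base models, a sequential risk-stratification tree built from the two
#' base models' realized sensitivity/specificity at the realized base rate,
#' generalization of the negative-symptom models to functional outcomes, and
#' (when supplied) transdiagnostic application to external cohorts. All
#' artifacts are written under `out_dir` as CSV/TSV/JSON.
#'
#' @param config Named list. Recognized entries: `cohort` (a `cohort_table` or
#'   a file path; if absent one is simulated from `cohort_config`), `cohort_config`
#'   (list passed to [cohort_config()]), `out_dir` (required), `seed`,
#'   `view` settings `loss`, `grid`, `inner_k`, `inner_r`, `balance`,
#'   `prior`, `posterior_method`, `rr` (intervention risk ratio for NNT),
#'   `external` (named list of external `cohort_table`s, e.g. ROP/ROD).
#' @return Invisibly, a list with the fitted models, reports, CVR profiles and
#'   the stratification tree.
#' @export
run_full_analysis <- function(config) {
  if (is.null(config[["out_dir"]])) stop("config$out_dir is required")
  out_dir <- config[["out_dir"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config[["seed"]] %||% 1L
  loss <- config[["loss"]] %||% "logistic"
  grid <- config[["grid"]] %||% 10^seq(3, -3, length.out = 7)
  inner_k <- config[["inner_k"]] %||% 5L
  inner_r <- config[["inner_r"]] %||% 10L
  balance <- config[["balance"]] %||% TRUE
  prior <- config[["prior"]] %||% c(1, 1)
  pmethod <- config[["posterior_method"]] %||% "grid_convolution"

  log_file <- file.path(out_dir, "run.log")
  logf <- function(stage, msg) {
    cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%H:%M:%S"), stage, msg),
        file = log_file, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      writeLines(name, file.path(out_dir, "FAILED_STAGE"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    logf(name, sprintf("done in %.1fs", proc.time()[["elapsed"]] - t0))
    res
  }

  cohort <- stage("cohort", {
    if (is.null(config[["cohort"]])) {
      cc <- do.call(cohort_config, utils::modifyList(list(seed = seed),
                                                    config[["cohort_config"]] %||% list()))
      generate_cohort(cc)
    } else if (is.character(config[["cohort"]])) {
      read_cohort(config[["cohort"]])
    } else config[["cohort"]]
  })
  cohort <- stage("label", add_outcome_labels(cohort))
  write_cohort(cohort, file.path(out_dir, "cohort_labelled.csv"))

  fits <- list()
  fits$sips_n <- stage("train_sips_n", fit_lso(
    cohort, view = "sips_n", loss = loss, grid = grid,
    inner_k = inner_k, inner_r = inner_r, seed = seed, balance = balance))
  fits$gyrification <- stage("train_gyrification", fit_lso(
    cohort, view = "gyrification", loss = loss, grid = grid,
    inner_k = inner_k, inner_r = inner_r, seed = seed, balance = balance,
    scheme = fits$sips_n$scheme))
  fits$stacked <- stage("stack", fit_stacked(
    fits[c("sips_n", "gyrification")], loss = loss, grid = grid, balance = balance))

  reports <- stage("evaluate", lapply(fits, function(f) {
    summary(f, prior = prior, posterior_method = pmethod)
  }))
  for (nm in names(fits)) {
    utils::write.csv(fits[[nm]]$scores,
                     file.path(out_dir, paste0("scores_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(lapply(reports, .report_to_list),
                       file.path(out_dir, "performance_reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  profiles <- stage("importance", lapply(fits[c("sips_n", "gyrification")], cvr_profile))
  for (nm in names(profiles)) {
    utils::write.table(as.data.frame(profiles[[nm]]),
                       file.path(out_dir, paste0("cvr_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  tree <- stage("stratify", {
    pretest <- mean(cohort$negsym_bad)
    t1 <- diagnostic_test("SIPS-N", reports$sips_n$metrics$SE, reports$sips_n$metrics$SP)
    t2 <- diagnostic_test("gyrification", reports$gyrification$metrics$SE,
                          reports$gyrification$metrics$SP)
    build_stratification_tree(pretest, list(t1, t2), rr = config[["rr"]])
  })
  jsonlite::write_json(list(pretest = tree$pretest, rr = tree$rr, nodes = tree$nodes),
                       file.path(out_dir, "stratification_tree.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  empirical <- stage("empirical_rates", {
    d <- data.frame(test_sips = fits$sips_n$scores$pred,
                    test_gyr = fits$gyrification$scores$pred,
                    negsym_bad = cohort$negsym_bad)
    empirical_branch_rates(d, c("test_sips", "test_gyr"))
  })

  generalization <- stage("generalize_gf", {
    out <- list()
    for (gf in c("gf_social_impaired", "gf_role_impaired")) {
      ygf <- cohort[[gf]]
      if (length(unique(ygf)) == 2L) {
        out[[gf]] <- lapply(fits, function(f) {
          .report_to_list(performance_report(f$scores$score, ygf,
                                             pred = f$scores$pred, prior = prior,
                                             posterior_method = pmethod))
        })
      }
    }
    out
  })

  external <- NULL
  if (!is.null(config[["external"]])) {
    external <- stage("generalize_external", {
      lapply(config[["external"]], function(ext) {
        ext <- add_outcome_labels(ext)
        lapply(fits, function(f) {
          pr <- predict(f, ext)
          .report_to_list(performance_report(pr$score, ext$negsym_bad, pred = pr$pred,
                                             prior = prior, posterior_method = pmethod))
        })
      })
    })
    jsonlite::write_json(external, file.path(out_dir, "external_reports.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(generalization, file.path(out_dir, "gf_generalization.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  snapshot <- config
  snapshot$cohort <- NULL; snapshot$external <- NULL
  snapshot$seed <- seed
  jsonlite::write_json(snapshot, file.path(out_dir, "config_snapshot.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  invisible(list(cohort = cohort, fits = fits, reports = reports,
                 profiles = profiles, tree = tree, empirical = empirical,
                 gf_generalization = generalization, external = external))
}
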