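# End-to-end orchestration: simulate (or load) -> preprocess -> stratify ->
# classify -> survival, driven by one YAML/list config, with a
# machine-readable run report. One root seed is fanned out to per-stage
# seeds by a fixed derivation so stages can be rerun in isolation.

PIPELINE_VERSION <- "1.0.0"

pipeline_defaults <- function() {
  list(mode = "synthetic",
       seed = 1L,
       out_dir = NULL,
       input_dir = NULL,             # user mode: directory from write_cohort()
       simulate = unclass(sim_config()),
       preprocess = unclass(preprocess_config()),
       stratify = list(enabled = TRUE, min_group_size = 3L,
                       censored_policy = "exclude", cutoff_months = NULL),
       classify = list(B = 500L, k = 7L, ridge_penalty = 1e-4,
                       threshold = 0.5),
       survival = list(alpha = 0.05, min_group_size = 3L))
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Validate and normalise a pipeline configuration
#'
#' Fills every omitted field with its default and checks cross-field
#' constraints; violations are reported together, each naming the offending
#' field path.
#'
#' @param config A named list, or a path to a YAML file.
#' @return The normalised config list (class `pipeline_config`). Warnings are
#'   emitted for precedence ambiguities (e.g. a fixed cut-off supplied while
#'   stratification is enabled).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("I/O error: missing config %s", config))
    config <- yaml::read_yaml(config) %||% list()
  }
  cfg <- merge_config(pipeline_defaults(), config)
  errors <- character(0)
  err <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))

  if (!cfg$mode %in% c("synthetic", "user")) err("mode: must be 'synthetic' or 'user'")
  if (cfg$mode == "user" && is.null(cfg$input_dir)) err("input_dir: required in user mode")
  sim <- cfg$simulate
  if (sim$n_patients < 2) err("simulate.n_patients: must be >= 2")
  if (!(sim$wavenumber_start < sim$wavenumber_end)) {
    err("simulate.wavenumber_start/wavenumber_end: start must be < end")
  }
  pp <- cfg$preprocess
  if (!(pp$quality_min < pp$quality_max)) {
    err("preprocess.quality_min/preprocess.quality_max: min must be < max")
  }
  if (pp$max_shift < 0) err("preprocess.max_shift: must be >= 0")
  if (pp$fingerprint_range[1] < sim$wavenumber_start ||
      pp$fingerprint_range[2] > sim$wavenumber_end) {
    err("preprocess.fingerprint_range: must lie inside the wavenumber axis")
  }
  if (cfg$classify$B < 10) err("classify.B: must be >= 10")
  if (cfg$stratify$min_group_size < 1) err("stratify.min_group_size: must be >= 1")
  if (length(errors)) {
    stop(paste(c("config error:", errors), collapse = "\n  "))
  }
  if (!is.null(cfg$stratify$cutoff_months) && isTRUE(cfg$stratify$enabled)) {
    warning("stratify.cutoff_months supplied while stratify.enabled is TRUE: ",
            "the data-driven cut-off overrides the supplied value")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> preprocess -> stratify -> classify ->
#' survival, writing intermediate artifacts and a `report.json` to the run
#' directory. Identical config and seed reproduce the report exactly,
#' timestamps aside. Any stage error aborts with the stage name and leaves a
#' partial report on disk.
#'
#' @param config A config list, path to YAML, or `pipeline_config`.
#' @param out_dir Run directory (overrides `config$out_dir`; default a
#'   tempdir subdirectory). Layout: `inputs/`, `intermediate/`, `results/`,
#'   `report.json`.
#' @return The run report (list of class `run_report`), invisibly also
#'   written as JSON.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("spectrosurv_run_")
  for (d in c("inputs", "intermediate", "results")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  seeds <- stage_seeds(cfg$seed)
  report <- list(version = PIPELINE_VERSION, seed = cfg$seed,
                 config = unclass_deep(cfg),
                 started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 stages = list())
  stage <- function(name, f) {
    message(sprintf("[spectrosurv] stage %s", name))
    tryCatch(f(), error = function(e) {
      report$failed_stage <<- name
      report$error <<- conditionMessage(e)
      write_report(report, out_dir)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- inputs -------------------------------------------------------------
  data <- stage("simulate", function() {
    if (cfg$mode == "synthetic") {
      sc <- do.call(sim_config, c(cfg$simulate[setdiff(names(cfg$simulate),
                                                       "seed")],
                                  list(seed = seeds[["simulate"]])))
      cohort <- simulate_cohort(sc)
      write_cohort(cohort, file.path(out_dir, "inputs"))
      report$stages$simulate <<- list(
        n_patients = sc$n_patients, core_size = sc$core_size,
        effect_size = sc$effect_size, seed = seeds[["simulate"]],
        output = "inputs/")
      list(cubes = cohort$cubes, masks = cohort$masks, cohort = cohort$cohort,
           refs = cohort$refs)
    } else {
      if (!file.exists(file.path(cfg$input_dir, "cohort.tsv"))) {
        stop(sprintf("missing cohort file %s (stratify inputs)",
                     file.path(cfg$input_dir, "cohort.tsv")))
      }
      d <- read_cohort_dir(cfg$input_dir)
      d$refs <- make_reference_spectra(d$cubes[[1]]$axis)
      report$stages$simulate <<- list(mode = "user", input = cfg$input_dir,
                                      n_patients = nrow(d$cohort))
      d
    }
  })

  # --- preprocess ---------------------------------------------------------
  ppcfg <- do.call(preprocess_config,
                   cfg$preprocess[names(cfg$preprocess) %in%
                                  names(formals(preprocess_config))])
  pp <- stage("preprocess", function() {
    per <- lapply(names(data$cubes), function(id) {
      preprocess_cube(data$cubes[[id]], data$masks[[id]], data$refs, ppcfg)
    })
    names(per) <- names(data$cubes)
    ds <- bind_datasets(lapply(per, `[[`, "dataset"))
    pp_report <- list(
      offsets = lapply(per, function(p) as.integer(p$offset)),
      n_tumour = vapply(per, `[[`, numeric(1), "n_tumour"),
      n_retained = vapply(per, `[[`, numeric(1), "n_retained"))
    writeLines(jsonlite::toJSON(pp_report, auto_unbox = FALSE, digits = NA),
               file.path(out_dir, "intermediate", "preprocess_report.json"))
    write_dataset_tsv(ds, file.path(out_dir, "intermediate", "dataset.tsv"))
    report$stages$preprocess <<- list(
      input = "inputs/", output = "intermediate/dataset.tsv",
      n_datapoints = nrow(ds$matrix),
      n_retained_per_patient = unname(pp_report$n_retained))
    ds
  })

  # --- stratify -----------------------------------------------------------
  strat <- stage("stratify", function() {
    if (isTRUE(cfg$stratify$enabled)) {
      s <- stratify_by_outcome(data$cohort, cfg$stratify$min_group_size,
                               cfg$stratify$censored_policy)
      cutoff <- s$cutoff_months
      writeLines(jsonlite::toJSON(list(cutoff_months = cutoff,
                                       statistic = s$statistic_at_cutoff,
                                       p_value = s$p_value_at_cutoff,
                                       profile = s$candidate_profile),
                                  auto_unbox = TRUE, digits = NA, na = "null"),
                 file.path(out_dir, "intermediate", "stratification.json"))
    } else {
      s <- NULL
      cutoff <- cfg$stratify$cutoff_months
      if (is.null(cutoff)) stop("no cut-off: stratify disabled and none supplied")
    }
    labels <- label_endpoint(data$cohort, cutoff, cfg$stratify$censored_policy)
    report$stages$stratify <<- list(
      input = "inputs/cohort.tsv", cutoff_months = cutoff,
      statistic = if (is.null(s)) NA else s$statistic_at_cutoff,
      n_high = sum(labels == "high"), n_low = sum(labels == "low"),
      n_excluded = sum(labels == "excluded"))
    list(cutoff = cutoff, labels = labels)
  })

  # --- classify -----------------------------------------------------------
  boot <- stage("classify", function() {
    b <- bootstrap_evaluate(pp, strat$labels, B = cfg$classify$B,
                            seed = seeds[["classify"]], k = cfg$classify$k,
                            ridge_penalty = cfg$classify$ridge_penalty,
                            threshold = cfg$classify$threshold)
    scored <- data$cohort
    scored$risk_label <- unname(strat$labels[scored$patient_id])
    scored$risk_label[scored$risk_label == "excluded"] <- NA
    scored$score <- unname(b$patient_scores[scored$patient_id])
    write_cohort_table(scored[!is.na(scored$score), ],
                       file.path(out_dir, "results", "scored_cohort.tsv"))
    writeLines(jsonlite::toJSON(list(
      median_auroc = b$median_auroc,
      median_sensitivity = b$median_sensitivity,
      median_specificity = b$median_specificity,
      dispersion = as.list(b$dispersion),
      n_replicates = b$n_replicates,
      patient_scores = as.list(b$patient_scores)),
      auto_unbox = TRUE, digits = NA),
      file.path(out_dir, "results", "classification.json"))
    report$stages$classify <<- list(
      input = "intermediate/dataset.tsv", B = cfg$classify$B,
      k = cfg$classify$k, seed = seeds[["classify"]],
      median_auroc = b$median_auroc,
      median_sensitivity = b$median_sensitivity,
      median_specificity = b$median_specificity,
      dispersion = as.list(b$dispersion),
      output = "results/scored_cohort.tsv")
    b
  })

  # --- survival -----------------------------------------------------------
  surv <- stage("survival", function() {
    scored_ids <- names(boot$patient_scores)
    cc <- data$cohort[match(scored_ids, data$cohort$patient_id), ]
    cox <- cox_fit(boot$patient_scores, cc$time_months, cc$event,
                   alpha = cfg$survival$alpha)
    rev <- reverse_analysis(boot$patient_scores, data$cohort,
                            cfg$survival$min_group_size, cfg$survival$alpha)
    write_km_tsv(rev$km_high, file.path(out_dir, "results", "km_high.tsv"))
    write_km_tsv(rev$km_low, file.path(out_dir, "results", "km_low.tsv"))
    writeLines(jsonlite::toJSON(list(
      cox = list(beta = cox$beta, hazard_ratio = cox$hazard_ratio,
                 ci_lower = cox$ci_lower, ci_upper = cox$ci_upper,
                 p_value = cox$p_value, standard_error = cox$standard_error,
                 separation = cox$separation),
      reverse = list(threshold = rev$threshold,
                     logrank_statistic = rev$logrank$statistic,
                     logrank_p = rev$logrank$p_value)),
      auto_unbox = TRUE, digits = NA, na = "null"),
      file.path(out_dir, "results", "survival.json"))
    report$stages$survival <<- list(
      input = "results/scored_cohort.tsv",
      cox_hazard_ratio = cox$hazard_ratio, cox_ci = c(cox$ci_lower, cox$ci_upper),
      cox_p = cox$p_value, cox_separation = cox$separation,
      reverse_threshold = rev$threshold,
      reverse_logrank_p = rev$logrank$p_value)
    list(cox = cox, reverse = rev)
  })

  report$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_report(report, out_dir)
  structure(c(report, list(out_dir = out_dir,
                           bootstrap = boot, survival_fits = surv,
                           cutoff = strat$cutoff)),
            class = "run_report")
}

write_report <- function(report, out_dir) {
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              na = "null", null = "null", pretty = TRUE),
             file.path(out_dir, "report.json"))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Write a spectral dataset as TSV
#'
#' Meta columns (patient_id, row, col) followed by one column per
#' fingerprint wavenumber (named `wn<value>`).
#'
#' @param dataset A `spectral_dataset`.
#' @param path Output path.
#' @export
write_dataset_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  m <- as.data.frame(dataset$matrix)
  names(m) <- sprintf("wn%g", dataset$axis)
  utils::write.table(cbind(dataset$meta, m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a spectral dataset written by [write_dataset_tsv()]
#'
#' @param path TSV path.
#' @return A `spectral_dataset`.
#' @export
read_dataset_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  wn_cols <- grep("^wn", names(df))
  structure(list(matrix = as.matrix(df[, wn_cols]),
                 axis = as.numeric(sub("^wn", "", names(df)[wn_cols])),
                 meta = df[, c("patient_id", "row", "col")]),
            class = "spectral_dataset")
}
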