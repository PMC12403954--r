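## ---- table IO, run configuration, pipeline runner ------------------------

covariate_columns <- c("subject_id", "group", "age", "sex", "tiv", "scanner", "visit")

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

#' Read and validate a biomarker table
#'
#' Accepts CSV or TSV (dialect sniffed from the header line). Requires the
#' covariate columns `subject_id`, `group`, `age`, `sex`, `tiv`, `scanner`,
#' `visit` plus at least one numeric biomarker column; rejects duplicate
#' subject-visit keys and non-finite biomarker values, reporting the
#' offending columns/rows.
#'
#' @param path file path.
#' @return data.frame with `sex` and `scanner` as factors.
#' @export
read_biomarker_table <- function(path) {
  d <- read_delim_auto(path)
  miss <- setdiff(covariate_columns, names(d))
  if (length(miss))
    stop_input("biomarker table lacks columns: %s", paste(miss, collapse = ", "))
  bio <- setdiff(names(d), covariate_columns)
  if (!length(bio)) stop_input("no biomarker columns found")
  bad <- bio[!vapply(d[bio], is.numeric, TRUE)]
  if (length(bad))
    stop_input("non-numeric biomarker columns: %s", paste(bad, collapse = ", "))
  key <- paste(d$subject_id, d$visit)
  if (anyDuplicated(key))
    stop_input("duplicate subject-visit rows: %s",
               paste(which(duplicated(key)), collapse = ", "))
  nf <- which(!stats::complete.cases(d[bio]) |
                apply(as.matrix(d[bio]), 1L, function(r) any(!is.finite(r))))
  if (length(nf))
    stop_input("non-finite biomarker values in rows: %s", paste(nf, collapse = ", "))
  d$sex <- factor(d$sex)
  d$scanner <- factor(d$scanner)
  d
}

#' Read and validate a clinical table
#'
#' CSV/TSV with `subject_id` and any of the standard clinical columns
#' (`edss`, `followup_edss` validated against the 0-10 half-point grid;
#' counts validated nonnegative). Missing values use the explicit `NA`
#' marker.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical_table <- function(path) {
  d <- read_delim_auto(path)
  if (!"subject_id" %in% names(d)) stop_input("clinical table needs 'subject_id'")
  if (anyDuplicated(d$subject_id))
    stop_input("duplicate subject_id rows: %s",
               paste(which(duplicated(d$subject_id)), collapse = ", "))
  for (v in intersect(c("edss", "followup_edss"), names(d))) {
    x <- d[[v]]
    bad <- which(!is.na(x) & (x < 0 | x > 10 | abs(x * 2 - round(x * 2)) > 1e-8))
    if (length(bad))
      stop_input("column '%s' off the EDSS half-point grid in rows: %s",
                 v, paste(bad, collapse = ", "))
  }
  for (v in intersect(c("n_relapses", "followup_relapses"), names(d))) {
    bad <- which(!is.na(d[[v]]) & d[[v]] < 0)
    if (length(bad))
      stop_input("negative counts in '%s' rows: %s", v, paste(bad, collapse = ", "))
  }
  d
}

#' Write a cohort to CSV files
#'
#' Writes `biomarkers.csv`, and when supplied `clinical.csv` and
#' `truth.csv`, plus a JSON run manifest recording the seed.
#'
#' @param dir output directory (created if needed).
#' @param biomarkers,clinical,truth data.frames (clinical/truth optional).
#' @param seed seed to record in the manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(dir, biomarkers, clinical = NULL, truth = NULL,
                             seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(biomarkers, file.path(dir, "biomarkers.csv"), row.names = FALSE)
  if (!is.null(clinical))
    utils::write.csv(clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  if (!is.null(truth))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = seed, files = list.files(dir)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a pipeline run configuration
#'
#' Reads a YAML configuration (or accepts an equivalent named list):
#' `biomarkers` (path, required), `clinical` (path, optional), `output_dir`,
#' `z_levels`, `z_max`, `C_max`, `folds`, `n_starts`, `cv_n_starts`,
#' `mcmc_iters`, `parsimony_delta`, and a mandatory `seed`. Referenced files
#' must exist at load time.
#'
#' @param config YAML path or named list.
#' @return validated configuration list of class `run_config`.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop_input("run config must set a seed")
  if (is.null(config$biomarkers)) stop_input("run config must point to a biomarker table")
  for (f in c("biomarkers", "clinical")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop_input("configured %s file does not exist: %s", f, config[[f]])
  }
  defaults <- list(output_dir = "zsustain_run", z_levels = c(1, 2, 3),
                   z_max = 5, C_max = 2L, folds = 10L, n_starts = 10L,
                   cv_n_starts = 5L, mcmc_iters = 5000L, parsimony_delta = 6,
                   stage_over = "all")
  config <- utils::modifyList(defaults, config)
  class(config) <- c("run_config", "list")
  config
}

#' Run the full subtyping pipeline
#'
#' Executes, in order: table reading, batch/covariate adjustment, control
#' matching, z-scoring, model fitting with cross-validated selection,
#' subject assignment (baseline, and follow-up visits scored with the
#' baseline-fitted model), and — when a clinical table is configured —
#' subtype characterization. All artifacts are written to the configured
#' output directory together with a JSON manifest (config, seed, stage
#' timings, selected model). Any stage failure halts with the stage name.
#'
#' @param config a [load_run_config()] input (YAML path or list).
#' @return the manifest list, invisibly; artifacts on disk:
#'   `zscores.csv`, `model.json`, `assignments.csv`,
#'   `positional_density_S*.csv`, `stability.json` (if follow-up visits
#'   exist), `stage_correlations.csv` / `dmt_response.csv` (if clinical),
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  manifest <- list(package = "zsustain",
                   version = as.character(utils::packageVersion("zsustain")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "output_dir")])
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop_input("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  tabs <- stage("read", {
    bio <- read_biomarker_table(config$biomarkers)
    clin <- if (!is.null(config$clinical)) read_clinical_table(config$clinical)
    list(bio = bio, clin = clin)
  })
  adj <- stage("preprocess", {
    adj <- adjust_batch_covariates(tabs$bio)
    jsonlite::write_json(attr(adj, "adjustment"),
                         file.path(out_dir, "adjustment_coefficients.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    hcs <- adj[adj$group == "HC" & adj$visit == "baseline", ]
    pats <- adj[adj$group != "HC" & adj$visit == "baseline", ]
    follow <- adj[adj$group != "HC" & adj$visit != "baseline", ]
    pairs <- match_controls(pats, hcs, seed = derive_seed(config$seed, "match"))
    matched <- hcs[match(pairs$hc_id, hcs$subject_id), ]
    z_pat <- compute_zscores(pats, matched)
    z_fu <- if (nrow(follow)) compute_zscores(follow, matched)
    list(z_pat = z_pat, z_fu = z_fu)
  })
  biomarker_cols <- setdiff(names(adj$z_pat), c("subject_id", "group", "visit"))
  utils::write.csv(rbind(adj$z_pat, adj$z_fu),
                   file.path(out_dir, "zscores.csv"), row.names = FALSE)
  es <- event_set(biomarker_cols, z_levels = config$z_levels, z_max = config$z_max)
  fit <- stage("fit", {
    fit_sustain(adj$z_pat, es, C_max = config$C_max, folds = config$folds,
                n_starts = config$n_starts, cv_n_starts = config$cv_n_starts,
                mcmc_iters = config$mcmc_iters,
                parsimony_delta = config$parsimony_delta,
                seed = derive_seed(config$seed, "fit"))
  })
  write_sustain_json(fit, file.path(out_dir, "model.json"))
  for (c in seq_along(fit$selected_models)) {
    pd <- fit$selected_models[[c]]$positional_density
    if (!is.null(pd))
      utils::write.csv(pd, file.path(out_dir, sprintf("positional_density_S%d.csv", c)))
  }
  assign_bl <- stage("assign", {
    a <- assign_subjects(adj$z_pat, fit, stage_over = config$stage_over)
    utils::write.csv(a, file.path(out_dir, "assignments.csv"), row.names = FALSE)
    a
  })
  if (!is.null(adj$z_fu) && nrow(adj$z_fu)) {
    assign_fu <- assign_subjects(adj$z_fu, fit, stage_over = config$stage_over)
    stab <- suppressWarnings(longitudinal_stability(assign_bl, assign_fu))
    jsonlite::write_json(stab, file.path(out_dir, "stability.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stability <- stab
  }
  if (!is.null(tabs$clin)) {
    char <- stage("characterize", {
      d <- merge(tabs$clin, assign_bl, by = "subject_id")
      vars <- intersect(c("edss", "n_relapses", "cvlt", "bvmt", "pasat",
                          "sdmt", "cowat"), names(d))
      covs <- d[, intersect(c("age", "sex", "disease_duration"), names(d)),
                drop = FALSE]
      sc <- stage_correlations(d$weighted_stage, d[vars], covariates = covs)
      utils::write.csv(sc, file.path(out_dir, "stage_correlations.csv"),
                       row.names = FALSE)
      resp <- tryCatch(dmt_response(tabs$clin, assign_bl), error = function(e) NULL)
      if (!is.null(resp))
        utils::write.csv(resp$rates, file.path(out_dir, "dmt_response.csv"),
                         row.names = FALSE)
      list(stage_correlations = sc, dmt_response = resp)
    })
    manifest$characterized <- TRUE
  } else {
    message("no clinical table configured; characterization skipped")
    manifest$characterized <- FALSE
  }
  manifest$selected_C <- fit$selected_C
  manifest$cvic <- as.list(fit$cvic)
  manifest$prevalence <- subtype_prevalence(assign_bl)
  manifest$timings <- timings
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
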