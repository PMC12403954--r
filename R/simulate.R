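## ---- synthetic cohorts with known ground truth ---------------------------

default_biomarkers <- function() {
  c("cortical_gm", "deep_gm", "cerebellar_gm", "cerebral_wm",
    "cerebellar_wm", "brainstem", "hippocampus", "mucca")
}

## realistic baseline volumes: ml for brain structures, mm^2 for the mean
## upper cervical cord area (MUCCA)
default_baselines <- function(biomarkers) {
  known <- c(cortical_gm = 500, deep_gm = 42, cerebellar_gm = 105,
             cerebral_wm = 460, cerebellar_wm = 26, brainstem = 22,
             hippocampus = 8.2, mucca = 72)
  out <- known[biomarkers]
  out[is.na(out)] <- 100
  names(out) <- biomarkers
  out
}

#' Configure a synthetic multi-scanner atrophy cohort
#'
#' Bundles every generator parameter: cohort sizes, the event grid, the
#' ground-truth subtype orderings and mixing fractions, the stage
#' distribution, scanner batch offsets, covariate effects (age, sex, TIV),
#' residual noise, and the clinical outcome model linking stage and subtype
#' to EDSS, relapse rate and progression hazard.
#'
#' Raw volumes are generated on a realistic ml scale (MUCCA in mm^2); the
#' analysis pipeline is invariant to this scale once z-scored. The patient
#' generator inverts the piecewise-linear z-score model: a patient at stage
#' `k` of subtype `c` has expected biomarker z equal to the subtype's
#' trajectory value, converted to a raw volume as
#' `predicted HC value - z * noise_sd` (atrophy lowers volume).
#'
#' @param n_hc,n_patients cohort sizes.
#' @param biomarkers biomarker names (default: 8 brain/spinal-cord volumes).
#' @param z_levels,z_max event thresholds and ceiling (see [event_set()]).
#' @param n_subtypes number of ground-truth subtypes.
#' @param orderings list of ground-truth orderings (default: random valid
#'   orderings drawn from `seed`).
#' @param fractions subtype mixing proportions (sum to 1).
#' @param stage_distribution probabilities over stages `0..E` (default
#'   uniform).
#' @param batch_offsets named numeric vector of additive per-scanner shifts
#'   (volume units).
#' @param age_slope,sex_offset,tiv_slope covariate effects per biomarker
#'   (scalar recycled): volume units per year, per male sex, per ml TIV.
#' @param noise_sd residual SD per biomarker in volume units (default 2% of
#'   baseline), which is also the z-to-volume conversion scale so that
#'   correctly adjusted z-scores have unit noise.
#' @param clinical_model list: `edss_intercept`, `edss_stage_slope`,
#'   `edss_sd`, `relapse_rate` (per subtype), `hazard` (per subtype, events
#'   per month), `admin_censor` (months), `duration_mean` (months).
#' @param stage_increment_mean mean of the truncated-at-zero (Poisson)
#'   stage advance at follow-up.
#' @param seed RNG seed recorded in the config.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_hc = 200L, n_patients = 300L,
                       biomarkers = default_biomarkers(),
                       z_levels = c(1, 2, 3), z_max = 5,
                       n_subtypes = 2L, orderings = NULL,
                       fractions = NULL,
                       stage_distribution = NULL,
                       batch_offsets = c(scannerA = 0, scannerB = 4),
                       age_slope = NULL, sex_offset = NULL, tiv_slope = NULL,
                       noise_sd = NULL,
                       clinical_model = list(),
                       stage_increment_mean = 2,
                       seed = 1L) {
  es <- event_set(biomarkers, z_levels = z_levels, z_max = z_max)
  B <- length(biomarkers)
  baselines <- default_baselines(biomarkers)
  if (is.null(noise_sd)) noise_sd <- 0.02 * baselines
  noise_sd <- rep_len(as.numeric(noise_sd), B)
  names(noise_sd) <- biomarkers
  if (any(noise_sd < 0)) stop_input("noise_sd must be nonnegative")
  if (n_hc < 1L) stop_input("n_hc must be >= 1")
  age_slope <- rep_len(as.numeric(age_slope %||% (-0.004 * baselines)), B)
  sex_offset <- rep_len(as.numeric(sex_offset %||% (0.05 * baselines)), B)
  tiv_slope <- rep_len(as.numeric(tiv_slope %||% (0.0004 * baselines)), B)
  if (is.null(fractions)) fractions <- rep(1 / n_subtypes, n_subtypes)
  if (length(fractions) != n_subtypes)
    stop_input("fractions must have length n_subtypes")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop_input("fractions must be nonnegative and sum to 1")
  if (is.null(orderings)) {
    orderings <- lapply(seq_len(n_subtypes), function(c)
      random_ordering(es, seed = derive_seed(seed, paste0("truth", c))))
  }
  if (length(orderings) != n_subtypes)
    stop_input("orderings must have length n_subtypes")
  for (o in orderings) assert_ordering(es, o)
  if (is.null(stage_distribution))
    stage_distribution <- rep(1 / (es$E + 1), es$E + 1L)
  if (length(stage_distribution) != es$E + 1L || any(stage_distribution < 0))
    stop_input("stage_distribution must be a nonnegative vector over stages 0..E")
  stage_distribution <- stage_distribution / sum(stage_distribution)
  cm <- utils::modifyList(list(
    edss_intercept = 1.5, edss_stage_slope = 0.15, edss_sd = 0.8,
    relapse_rate = rep(1.5, n_subtypes),
    hazard = rep(0.015, n_subtypes),
    admin_censor = 60, duration_mean = 36
  ), clinical_model)
  cm$relapse_rate <- rep_len(cm$relapse_rate, n_subtypes)
  cm$hazard <- rep_len(cm$hazard, n_subtypes)
  if (any(cm$relapse_rate < 0) || any(cm$hazard < 0))
    stop_input("relapse rates and hazards must be nonnegative")
  structure(
    list(n_hc = as.integer(n_hc), n_patients = as.integer(n_patients),
         biomarkers = biomarkers, event_set = es, baselines = baselines,
         n_subtypes = as.integer(n_subtypes), orderings = orderings,
         fractions = fractions, stage_distribution = stage_distribution,
         batch_offsets = batch_offsets,
         age_slope = stats::setNames(age_slope, biomarkers),
         sex_offset = stats::setNames(sex_offset, biomarkers),
         tiv_slope = stats::setNames(tiv_slope, biomarkers),
         noise_sd = noise_sd, clinical_model = cm,
         stage_increment_mean = stage_increment_mean, seed = as.integer(seed)),
    class = "sim_config"
  )
}

## covariate draws shared by both cohorts
draw_covariates <- function(n, config) {
  data.frame(
    age = stats::runif(n, 20, 60),
    sex = factor(sample(c("F", "M"), n, replace = TRUE), levels = c("F", "M")),
    tiv = stats::rnorm(n, 1450, 110),
    scanner = factor(sample(names(config$batch_offsets), n, replace = TRUE),
                     levels = names(config$batch_offsets)),
    stringsAsFactors = FALSE
  )
}

## expected raw volume from covariates + batch, before disease and noise
structural_mean <- function(cov, config) {
  n <- nrow(cov)
  B <- length(config$biomarkers)
  M <- matrix(rep(config$baselines, each = n), n, B)
  M <- M +
    outer(cov$age - 40, config$age_slope) +
    outer(as.numeric(cov$sex == "M"), config$sex_offset) +
    outer(cov$tiv - 1450, config$tiv_slope)
  M + config$batch_offsets[as.character(cov$scanner)]
  # note: batch shift applied uniformly to all biomarkers
}

#' Generate a healthy-control cohort
#'
#' Volumes follow `baseline + covariate effects + scanner offset + Gaussian
#' noise`; the group label is `"HC"`.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return a biomarker table (data.frame): `subject_id`, `group`, `age`,
#'   `sex`, `tiv`, `scanner`, `visit`, then one column per biomarker.
#' @export
generate_hc_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  maybe_seed(seed %||% derive_seed(config$seed, "hc"))
  n <- config$n_hc
  cov <- draw_covariates(n, config)
  M <- structural_mean(cov, config)
  noise <- matrix(stats::rnorm(n * length(config$biomarkers)), n) %*%
    diag(config$noise_sd, length(config$noise_sd))
  vols <- M + noise
  colnames(vols) <- config$biomarkers
  cbind(data.frame(subject_id = sprintf("HC%04d", seq_len(n)), group = "HC",
                   stringsAsFactors = FALSE),
        cov, visit = "baseline", as.data.frame(vols))
}

#' Generate a patient cohort with known subtypes and stages
#'
#' Each patient draws a subtype from the mixing fractions and a stage from
#' the stage distribution; the expected z of each biomarker is the
#' subtype trajectory value at that stage, converted to a raw volume by
#' subtracting `z * noise_sd` from the predicted healthy value (atrophy
#' lowers volume), then covariate/batch structure and Gaussian noise are
#' added.
#'
#' @inheritParams generate_hc_cohort
#' @param group group label for the patients (default `"MS"`).
#' @return list with `biomarkers` (table as in [generate_hc_cohort()]) and
#'   `truth` (data.frame: `subject_id`, `subtype`, `stage`, covariates).
#' @export
generate_patient_cohort <- function(config, seed = NULL, group = "MS") {
  stopifnot(inherits(config, "sim_config"))
  maybe_seed(seed %||% derive_seed(config$seed, "patients"))
  es <- config$event_set
  n <- config$n_patients
  cov <- draw_covariates(n, config)
  subtype <- sample.int(config$n_subtypes, n, replace = TRUE,
                        prob = config$fractions)
  stage <- sample(0:es$E, n, replace = TRUE, prob = config$stage_distribution)
  G <- lapply(config$orderings, function(o) traj_matrix(es, o)) # (E+1) x B
  Zexp <- t(vapply(seq_len(n), function(i) G[[subtype[i]]][stage[i] + 1L, ],
                   numeric(length(config$biomarkers))))
  M <- structural_mean(cov, config)
  noise <- matrix(stats::rnorm(n * length(config$biomarkers)), n) %*%
    diag(config$noise_sd, length(config$noise_sd))
  vols <- M - Zexp %*% diag(config$noise_sd, length(config$noise_sd)) + noise
  colnames(vols) <- config$biomarkers
  ids <- sprintf("PT%04d", seq_len(n))
  bio <- cbind(data.frame(subject_id = ids, group = group,
                          stringsAsFactors = FALSE),
               cov, visit = "baseline", as.data.frame(vols))
  truth <- cbind(data.frame(subject_id = ids, subtype = subtype, stage = stage,
                            stringsAsFactors = FALSE), cov)
  list(biomarkers = bio, truth = truth)
}

## snap to the EDSS half-point ordinal grid, clipped to [0, 10]
snap_edss <- function(x) pmin(10, pmax(0, round(x * 2) / 2))

#' Generate stage- and subtype-linked clinical outcomes
#'
#' EDSS is a monotone function of true stage plus ordinal noise on the
#' half-point grid; relapse counts are Poisson with subtype-specific rates;
#' follow-up time and progression events are exponential with
#' subtype-specific hazards under administrative censoring; the follow-up
#' EDSS is drawn consistently with the progression flag (increase at or
#' above the disability-worsening threshold only when an event occurred).
#'
#' @param truth ground-truth table from [generate_patient_cohort()].
#' @param config a [sim_config()].
#' @param seed optional seed override.
#' @return clinical table (data.frame): `subject_id`, `age`, `sex`,
#'   `education`, `disease_duration`, `n_relapses`, `edss`, cognitive
#'   scores, `followup_time`, `progression_event`, `followup_edss`,
#'   `followup_relapses`, `treatment`.
#' @export
generate_clinical <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!nrow(truth)) stop_input("empty ground-truth table")
  maybe_seed(seed %||% derive_seed(config$seed, "clinical"))
  cm <- config$clinical_model
  n <- nrow(truth)
  st <- truth$stage
  sub <- truth$subtype
  edss <- snap_edss(cm$edss_intercept + cm$edss_stage_slope * st +
                      stats::rnorm(n, 0, cm$edss_sd))
  n_relapses <- stats::rpois(n, cm$relapse_rate[sub])
  t_event <- ifelse(cm$hazard[sub] > 0,
                    stats::rexp(n, pmax(cm$hazard[sub], 1e-12)), Inf)
  followup_time <- pmin(t_event, cm$admin_censor)
  progression_event <- as.integer(t_event <= cm$admin_censor)
  thr <- ifelse(edss <= 5.5, 1.0, 0.5)
  followup_edss <- ifelse(
    progression_event == 1L,
    snap_edss(edss + thr + sample(c(0, 0.5), n, replace = TRUE)),
    ## non-progressors: change stays strictly below the worsening threshold
    snap_edss(edss + sample(c(-0.5, 0, 0.5), n, replace = TRUE) *
                ifelse(edss > 5.5, 0, 1) - ifelse(edss > 5.5, 0.5, 0) *
                sample(0:1, n, replace = TRUE))
  )
  followup_edss <- ifelse(progression_event == 1L, pmax(followup_edss, edss + thr),
                          followup_edss)
  cog_base <- c(cvlt = 85, bvmt = 35, pasat = 50, sdmt = 50, cowat = 25)
  cog <- vapply(names(cog_base), function(v)
    round(cog_base[[v]] - 0.6 * st + stats::rnorm(n, 0, 6)), numeric(n))
  out <- data.frame(
    subject_id = truth$subject_id,
    age = truth$age, sex = truth$sex,
    education = sample(9:18, n, replace = TRUE),
    disease_duration = round(stats::rexp(n, 1 / cm$duration_mean), 1),
    n_relapses = n_relapses, edss = edss,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(cog))
  out$followup_time <- round(followup_time, 2)
  out$progression_event <- progression_event
  out$followup_edss <- followup_edss
  out$followup_relapses <- stats::rpois(n, cm$relapse_rate[sub] *
                                          followup_time / cm$admin_censor)
  out$treatment <- sample(c("DMT", "immunosuppressant"), n, replace = TRUE,
                          prob = c(0.6, 0.4))
  out
}

#' Generate a follow-up scan table from advanced true stages
#'
#' Each subject keeps its true subtype; the true stage advances by a
#' Poisson (hence nonnegative) increment capped at `E`, and volumes are
#' regenerated from the advanced stage with fresh noise.
#'
#' @inheritParams generate_clinical
#' @param increment_mean mean stage advance; `0` keeps every stage fixed.
#' @return list with `biomarkers` (visit = `"followup"`) and `truth` (the
#'   advanced ground truth).
#' @export
generate_followup <- function(truth, config, seed = NULL,
                              increment_mean = config$stage_increment_mean) {
  stopifnot(inherits(config, "sim_config"))
  maybe_seed(seed %||% derive_seed(config$seed, "followup"))
  es <- config$event_set
  n <- nrow(truth)
  inc <- if (increment_mean <= 0) rep(0L, n) else stats::rpois(n, increment_mean)
  stage2 <- pmin(truth$stage + inc, es$E)
  cov <- truth[, c("age", "sex", "tiv", "scanner")]
  G <- lapply(config$orderings, function(o) traj_matrix(es, o))
  Zexp <- t(vapply(seq_len(n), function(i) G[[truth$subtype[i]]][stage2[i] + 1L, ],
                   numeric(length(config$biomarkers))))
  M <- structural_mean(cov, config)
  noise <- matrix(stats::rnorm(n * length(config$biomarkers)), n) %*%
    diag(config$noise_sd, length(config$noise_sd))
  vols <- M - Zexp %*% diag(config$noise_sd, length(config$noise_sd)) + noise
  colnames(vols) <- config$biomarkers
  bio <- cbind(data.frame(subject_id = truth$subject_id, group = "MS",
                          stringsAsFactors = FALSE),
               cov, visit = "followup", as.data.frame(vols))
  truth2 <- truth
  truth2$stage <- stage2
  list(biomarkers = bio, truth = truth2)
}
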