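## ---- subtype / stage assignment and longitudinal stability ---------------

## log stage-likelihood matrix (n x (E+1)) for one ordering, reused by both
## the subtype rule and the weighted stage
assignment_logdens <- function(Z, es, models) {
  lapply(models, function(m) stage_logdens_matrix(Z, es, traj_matrix(es, m$ordering)))
}

#' Assign subjects to subtypes and probability-weighted stages
#'
#' For each subject the stage-0 likelihood `L_0 = prod_b Normal(z_b; 0, 1)`
#' is compared with each subtype's likelihood
#' `L_c = f_c * E^{-1} * sum_{k=1}^{E} P(x | S_c, k)` (stage 0 excluded from
#' the subtype sum: it is the normal-appearing alternative). A subject is
#' flagged normal-appearing (NA) when `L_0 >= max_c L_c` (boundary ties are
#' resolved conservatively as NA); otherwise the maximum-likelihood subtype
#' is assigned. The posterior column reports
#' `(L_0, L_1, ..., L_C)` normalized to 1.
#'
#' The weighted stage averages the stage over the joint posterior
#' `P(c, k | x) \propto f_c * (E+1)^{-1} * P(x | S_c, k)` on the full grid
#' `k = 0..E`; set `stage_over = "ml"` to average within the assigned
#' subtype only.
#'
#' @param Z z-score matrix or data.frame (with a `subject_id` column if a
#'   data.frame; otherwise row order identifies subjects).
#' @param fit a `sustain_fit` (its selected models are used) or a list of
#'   subtype models.
#' @param es event set; taken from `fit` when it is a `sustain_fit`.
#' @param stage_over `"all"` (default) or `"ml"`: whether the weighted stage
#'   averages over all subtypes or only the maximum-likelihood one.
#' @param subtype_stage0 include stage 0 in the subtype likelihood sums
#'   (default `FALSE`, matching the NA-vs-subtype contrast).
#' @return data.frame of class `assignment_table`: `subject_id`, `na_flag`,
#'   `ml_subtype` (`"NA"` or `"S1"..`), `weighted_stage`, posterior columns
#'   `p_na`, `p_S1`, ... and `visit` if present in `Z`.
#' @export
assign_subjects <- function(Z, fit, es = NULL, stage_over = c("all", "ml"),
                            subtype_stage0 = FALSE) {
  stage_over <- match.arg(stage_over)
  if (inherits(fit, "sustain_fit")) {
    es <- fit$event_set
    models <- fit$selected_models
  } else {
    if (is.null(es)) stop_input("supply an event_set when 'fit' is a model list")
    models <- fit
  }
  if (is.null(models) || !length(models)) stop_input("no fitted model supplied")
  ids <- NULL
  visit <- NULL
  if (is.data.frame(Z)) {
    ids <- if ("subject_id" %in% names(Z)) Z$subject_id
    visit <- if ("visit" %in% names(Z)) Z$visit
  }
  Zm <- as_z_matrix(Z, es)
  n <- nrow(Zm)
  if (is.null(ids)) ids <- sprintf("subj%04d", seq_len(n))
  E <- es$E
  C <- length(models)
  f <- vapply(models, `[[`, 1.0, "fraction")
  LD <- assignment_logdens(Zm, es, models) # list of n x (E+1) log densities

  ## log L_0: all-normal profile
  logL0 <- rowSums(stats::dnorm(Zm, 0, rep(es$sigma, each = n), log = TRUE))

  ## subtype likelihoods (stage 0 excluded unless requested)
  k_cols <- if (subtype_stage0) seq_len(E + 1L) else 2:(E + 1L)
  logLc <- vapply(seq_len(C), function(c) {
    row_logsumexp(LD[[c]][, k_cols, drop = FALSE]) - log(length(k_cols)) + log(f[c])
  }, numeric(n))
  logLc <- matrix(logLc, nrow = n)

  best_c <- max.col(logLc, ties.method = "first")
  best_logLc <- logLc[cbind(seq_len(n), best_c)]
  na_flag <- logL0 >= best_logLc # ties -> NA, conservative
  ml_subtype <- ifelse(na_flag, "NA", paste0("S", best_c))

  post_all <- cbind(logL0, logLc)
  post <- exp(post_all - apply(post_all, 1L, max))
  post <- post / rowSums(post)
  colnames(post) <- c("p_na", paste0("p_S", seq_len(C)))

  ## weighted stage over the joint (c, k) posterior on k = 0..E
  if (stage_over == "all") {
    ## joint posterior over the C*(E+1) grid, normalized per subject
    J <- do.call(cbind, lapply(seq_len(C), function(c) LD[[c]] + log(f[c])))
    m <- apply(J, 1L, max)
    Jn <- exp(J - m)
    tot <- rowSums(Jn)
    kgrid <- rep(0:E, times = C)
    weighted_stage <- as.numeric(Jn %*% kgrid) / tot
  } else {
    weighted_stage <- vapply(seq_len(n), function(i) {
      a <- LD[[best_c[i]]][i, ]
      p <- exp(a - max(a))
      sum((0:E) * p) / sum(p)
    }, numeric(1))
  }

  out <- data.frame(subject_id = ids, na_flag = na_flag,
                    ml_subtype = ml_subtype,
                    weighted_stage = weighted_stage,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(post))
  if (!is.null(visit)) out$visit <- visit
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Longitudinal subtype stability and stage progression
#'
#' Pairs baseline and follow-up assignments by `subject_id` and reports:
#' (a) the proportion of subjects with the same classification at both
#' visits or moving from normal-appearing (NA) to a subtype; (b) the
#' proportion with the same subtype after excluding subjects NA at both
#' visits; and (c) stage progression categories (lower / same / higher)
#' using an equality tolerance on the weighted stage.
#'
#' @param baseline,followup `assignment_table`s (from [assign_subjects()],
#'   the follow-up scored with the baseline-fitted model).
#' @param stage_tol absolute stage difference counted as "same"
#'   (default 0.5).
#' @return list with `n_pairs`, `stability` (proportion under rule (a)),
#'   `stability_nonNA` (rule (b)) with its `n_nonNA`, and `stage_progression`
#'   (named proportions lower/same/higher). Unpaired subjects are dropped
#'   with a warning.
#' @export
longitudinal_stability <- function(baseline, followup, stage_tol = 0.5) {
  need <- c("subject_id", "ml_subtype", "weighted_stage")
  for (nm in need) {
    if (!nm %in% names(baseline) || !nm %in% names(followup))
      stop_input("assignment tables need column '%s'", nm)
  }
  m <- merge(baseline[, need], followup[, need], by = "subject_id",
             suffixes = c("_bl", "_fu"))
  n_un <- nrow(baseline) + nrow(followup) - 2L * nrow(m)
  if (n_un > 0L)
    warning(sprintf("%d unpaired subject-visit rows excluded", n_un), call. = FALSE)
  if (!nrow(m)) stop_input("no paired subjects")
  same <- m$ml_subtype_bl == m$ml_subtype_fu
  na_to_sub <- m$ml_subtype_bl == "NA" & m$ml_subtype_fu != "NA"
  stable_a <- same | na_to_sub
  both_na <- m$ml_subtype_bl == "NA" & m$ml_subtype_fu == "NA"
  non_na <- !both_na
  stable_b <- same[non_na]
  d <- m$weighted_stage_fu - m$weighted_stage_bl
  cat3 <- ifelse(abs(d) < stage_tol, "same", ifelse(d > 0, "higher", "lower"))
  list(
    n_pairs = nrow(m),
    stability = mean(stable_a),
    n_nonNA = sum(non_na),
    stability_nonNA = if (sum(non_na)) mean(stable_b) else NA_real_,
    stage_progression = c(lower = mean(cat3 == "lower"),
                          same = mean(cat3 == "same"),
                          higher = mean(cat3 == "higher"))
  )
}

#' Subtype prevalence table
#'
#' Counts and percentages of each assigned class (NA and each subtype).
#'
#' @param assignments an `assignment_table` or any data.frame with an
#'   `ml_subtype` column.
#' @return data.frame with `subtype`, `n`, `percent`.
#' @export
subtype_prevalence <- function(assignments) {
  tab <- table(assignments$ml_subtype)
  data.frame(subtype = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / sum(tab),
             stringsAsFactors = FALSE)
}
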