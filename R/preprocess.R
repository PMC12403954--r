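## ---- harmonization, control matching, z-scoring --------------------------

#' Remove batch and covariate effects while preserving group effects
#'
#' Per biomarker, fits the ordinary least-squares model
#' `value ~ batch + covariates + group` and returns the values minus the
#' fitted batch and covariate contributions; the group contribution and the
#' residual are retained, and values are re-centered at the covariate means
#' (so the output stays on the original volume scale).
#'
#' A diagnostic group observed on only one scanner makes batch and group
#' effects inseparable; by default this raises an error (silent confounded
#' adjustment would corrupt the group effects the model is meant to
#' preserve). Set `allow_confounded = TRUE` to proceed with the aliased
#' coefficients dropped.
#'
#' @param table biomarker table (see [generate_hc_cohort()] layout).
#' @param biomarkers columns to adjust (default: all numeric columns apart
#'   from the covariates).
#' @param batch_var,group_var column names of the scanner batch and group
#'   label.
#' @param covariates covariate column names (default age, sex, tiv).
#' @param allow_confounded proceed despite batch/group confounding.
#' @return the table with adjusted biomarker values; the fitted adjustment
#'   coefficients are attached as attribute `"adjustment"` (a named list per
#'   biomarker, exportable as JSON for audit).
#' @export
adjust_batch_covariates <- function(table, biomarkers = NULL,
                                    batch_var = "scanner",
                                    covariates = c("age", "sex", "tiv"),
                                    group_var = "group",
                                    allow_confounded = FALSE) {
  if (is.null(biomarkers)) {
    covcols <- c("subject_id", "visit", batch_var, group_var, covariates)
    biomarkers <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                          covcols)
  }
  for (v in c(batch_var, group_var, covariates, biomarkers)) {
    if (!v %in% names(table)) stop_input("column '%s' not found", v)
  }
  if (anyNA(table[, c(batch_var, group_var, covariates)]))
    stop_input("missing covariate/batch/group values in rows entering adjustment")
  batch <- factor(table[[batch_var]])
  group <- factor(table[[group_var]])
  if (min(table(batch)) < 2L) stop_input("need >= 2 subjects per batch")

  ## degenerate terms (single batch, constant covariate, single group)
  ## carry no contribution and are dropped from the model
  usable <- function(x) {
    if (is.numeric(x)) stats::sd(x) > 0 else length(unique(x)) > 1L
  }
  terms_use <- c(
    if (usable(batch)) batch_var,
    covariates[vapply(table[covariates], usable, TRUE)],
    if (usable(group)) group_var
  )
  if (!length(terms_use)) { # nothing to remove: output equals input
    attr(table, "adjustment") <- stats::setNames(
      rep(list(list()), length(biomarkers)), biomarkers)
    return(table)
  }

  ## confounding check: batch and group inseparable (e.g. each group on its
  ## own scanner) shows up as a rank-deficient design
  rhs <- paste(terms_use, collapse = " + ")
  mf <- table[, unique(c(batch_var, covariates, group_var))]
  mf[[batch_var]] <- batch
  mf[[group_var]] <- group
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    if (!allow_confounded)
      stop_input("rank-deficient adjustment design; collinear columns: %s",
                 paste(aliased, collapse = ", "))
    warning(sprintf("confounded adjustment design; dropping: %s",
                    paste(aliased, collapse = ", ")), call. = FALSE)
  }

  num_cov <- covariates[vapply(table[covariates], is.numeric, TRUE)]
  coefs <- list()
  out <- table
  for (b in biomarkers) {
    dat <- mf
    dat$.y <- table[[b]]
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
    beta <- stats::coef(fit)
    beta[is.na(beta)] <- 0
    Xb <- stats::model.matrix(fit)
    keep <- colnames(Xb)
    is_batch <- startsWith(keep, batch_var)
    is_covar <- vapply(keep, function(cn) any(startsWith(cn, covariates)) &&
                         !startsWith(cn, group_var), TRUE)
    contrib_cols <- keep[(is_batch | is_covar) & keep != "(Intercept)"]
    Xc <- Xb[, contrib_cols, drop = FALSE]
    ## re-center: remove contributions relative to their sample means
    Xc_centered <- sweep(Xc, 2L, colMeans(Xc))
    out[[b]] <- table[[b]] - drop(Xc_centered %*% beta[contrib_cols])
    coefs[[b]] <- as.list(beta[names(beta) %in% c("(Intercept)", contrib_cols) |
                                 startsWith(names(beta), group_var)])
  }
  attr(out, "adjustment") <- coefs
  out
}

#' Greedy 1:1 nearest-neighbour matching of controls to patients
#'
#' Matches one healthy control to each patient by nearest standardized-age
#' distance with exact sex matching, greedily and without replacement.
#' Patient order is randomized under a fixed seed by default (greedy results
#' depend on order); set `shuffle = FALSE` for the as-given order.
#'
#' @param patients,hcs biomarker tables.
#' @param match_on covariates to match on: the first must be numeric
#'   (standardized distance), any factor entries are matched exactly.
#'   Default `c("age", "sex")`.
#' @param ratio controls per patient (currently 1).
#' @param shuffle randomize patient order (default TRUE).
#' @param seed seed for the shuffle.
#' @return data.frame with `patient_id` and `hc_id`.
#' @export
match_controls <- function(patients, hcs, match_on = c("age", "sex"),
                           ratio = 1L, shuffle = TRUE, seed = 1L) {
  if (ratio != 1L) stop_input("only 1:1 matching is supported")
  if (nrow(hcs) < nrow(patients))
    stop_input("fewer controls (%d) than patients (%d)", nrow(hcs), nrow(patients))
  is_num <- vapply(patients[match_on], is.numeric, TRUE)
  num_vars <- match_on[is_num]
  cat_vars <- match_on[!is_num]
  mu <- vapply(num_vars, function(v) mean(c(patients[[v]], hcs[[v]])), 0)
  sdv <- vapply(num_vars, function(v) stats::sd(c(patients[[v]], hcs[[v]])), 0)
  sdv[sdv == 0] <- 1
  std <- function(df) {
    m <- vapply(num_vars, function(v) (df[[v]] - mu[[v]]) / sdv[[v]],
                numeric(nrow(df)))
    matrix(m, nrow = nrow(df))
  }
  Pm <- std(patients)
  Hm <- std(hcs)
  ord <- seq_len(nrow(patients))
  if (shuffle) {
    maybe_seed(seed)
    ord <- sample(ord)
  }
  taken <- rep(FALSE, nrow(hcs))
  pid <- character(nrow(patients))
  hid <- character(nrow(patients))
  unmatched <- character(0)
  for (i in ord) {
    ok <- !taken
    for (v in cat_vars) ok <- ok & (as.character(hcs[[v]]) == as.character(patients[[v]][i]))
    if (!any(ok)) {
      unmatched <- c(unmatched, patients$subject_id[i])
      next
    }
    d <- colSums((t(Hm) - Pm[i, ])^2)
    d[!ok] <- Inf
    j <- which.min(d)
    taken[j] <- TRUE
    pid[i] <- patients$subject_id[i]
    hid[i] <- hcs$subject_id[j]
  }
  if (length(unmatched))
    stop_input("insufficient matching controls for patients: %s",
               paste(unmatched, collapse = ", "))
  data.frame(patient_id = pid, hc_id = hid, stringsAsFactors = FALSE)
}

#' Atrophy z-scores relative to matched healthy controls
#'
#' Per biomarker, fits `value ~ covariates` (ordinary least squares,
#' Gaussian identity link) on the matched controls, computes
#' `(observed - predicted) / SD(control residuals)` for every subject, and
#' returns the sign-flipped value so that atrophy (a smaller volume than
#' predicted) is a positive z-score.
#'
#' @param subjects biomarker table to score (patients, controls, or both).
#' @param matched_hcs biomarker table of the matched reference controls
#'   (already batch/covariate-adjusted, like `subjects`).
#' @param biomarkers biomarker columns (default: those of the event set
#'   layout — all numeric non-covariate columns).
#' @param covariates reference-model covariates (default age and sex).
#' @return data.frame of class `zscore_matrix`: `subject_id` (+ `group`,
#'   `visit` when present) and one z column per biomarker; the per-biomarker
#'   reference fits are attached as attribute `"reference"`.
#' @export
compute_zscores <- function(subjects, matched_hcs, biomarkers = NULL,
                            covariates = c("age", "sex")) {
  if (!nrow(matched_hcs)) stop_input("empty matched control set")
  if (is.null(biomarkers)) {
    covcols <- c("subject_id", "visit", "scanner", "group", "age", "sex", "tiv",
                 covariates)
    biomarkers <- setdiff(names(subjects)[vapply(subjects, is.numeric, TRUE)],
                          covcols)
  }
  rhs <- paste(covariates, collapse = " + ")
  keep <- intersect(c("subject_id", "group", "visit"), names(subjects))
  out <- subjects[, keep, drop = FALSE]
  ref <- list()
  for (b in biomarkers) {
    fit <- stats::lm(stats::as.formula(paste(b, "~", rhs)), data = matched_hcs)
    res_sd <- sqrt(sum(stats::residuals(fit)^2) / fit$df.residual)
    if (!is.finite(res_sd) || res_sd < 1e-10 * (1 + abs(mean(matched_hcs[[b]]))))
      stop_input("degenerate control sample for '%s' (zero residual SD)", b)
    pred <- stats::predict(fit, newdata = subjects)
    out[[b]] <- -(subjects[[b]] - pred) / res_sd # positive z = atrophy
    ref[[b]] <- list(coef = as.list(stats::coef(fit)), residual_sd = res_sd)
  }
  attr(out, "reference") <- ref
  class(out) <- c("zscore_matrix", "data.frame")
  out
}
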