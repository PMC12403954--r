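## ---- clinical / MRI characterization of subtypes and stages --------------

#' Flag EDSS disability progression
#'
#' Progression is an EDSS increase of at least 1.0 when the baseline EDSS is
#' 5.5 or lower, or at least 0.5 when the baseline exceeds 5.5. A missing
#' follow-up score yields `NA`, not `FALSE`.
#'
#' @param baseline_edss,followup_edss numeric vectors on the 0-10 half-point
#'   grid.
#' @return logical vector.
#' @examples
#' flag_edss_progression(3.0, 4.0)  # TRUE
#' flag_edss_progression(6.0, 6.5)  # TRUE
#' flag_edss_progression(3.0, 3.5)  # FALSE
#' @export
flag_edss_progression <- function(baseline_edss, followup_edss) {
  check_grid <- function(x) {
    bad <- !is.na(x) & (x < 0 | x > 10 | abs(x * 2 - round(x * 2)) > 1e-8)
    if (any(bad)) stop_input("EDSS values off the 0-10 half-point grid")
  }
  check_grid(baseline_edss)
  check_grid(followup_edss)
  n <- max(length(baseline_edss), length(followup_edss))
  b <- rep_len(baseline_edss, n)
  fu <- rep_len(followup_edss, n)
  delta <- fu - b
  ifelse(is.na(b) | is.na(fu), NA,
         ifelse(b <= 5.5, delta >= 1.0, delta >= 0.5))
}

#' Flag conversion to secondary progressive disease
#'
#' Conversion requires disability progression (per
#' [flag_edss_progression()] against the baseline score) sustained for at
#' least 6 months, with no relapse inside the sustaining window, and a
#' resulting EDSS of 4 or more. Subjects with less than 6 months of
#' follow-up return `NA`.
#'
#' @param records data.frame of one subject's longitudinal course: columns
#'   `time` (months from baseline; the row at `time == 0` is baseline),
#'   `edss`, and `relapse` (logical/0-1 flag at that assessment).
#' @return single logical (or `NA`).
#' @export
flag_spms_conversion <- function(records) {
  need <- c("time", "edss", "relapse")
  if (!all(need %in% names(records))) stop_input("records need columns time, edss, relapse")
  records <- records[order(records$time), ]
  if (max(records$time) - min(records$time) < 6) return(NA)
  base <- records$edss[1L]
  prog <- flag_edss_progression(base, records$edss)
  for (i in which(prog %in% TRUE)) {
    t0 <- records$time[i]
    later <- which(records$time >= t0 + 6)
    if (!length(later)) next # progression not yet observable for 6 months
    span <- which(records$time >= t0 & records$time <= records$time[later[1L]])
    sustained <- all(prog[span] %in% TRUE)
    relapse_free <- !any(records$relapse[span] > 0)
    resulting_edss <- records$edss[later[1L]]
    if (sustained && relapse_free && resulting_edss >= 4) return(TRUE)
  }
  FALSE
}

#' Covariate-adjusted Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Residualizes the variable on the covariates by ordinary least squares,
#' runs the Kruskal-Wallis rank test on the residuals across groups, and
#' follows up with pairwise Dunn z-tests (tie-corrected), reporting raw and
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param variable numeric outcome.
#' @param groups group factor (>= 2 levels with >= 3 subjects each).
#' @param covariates optional data.frame of adjustment covariates.
#' @return list with `statistic` (H), `df`, `p_value`, and `posthoc`
#'   (data.frame: `group1`, `group2`, `z`, `p_raw`, `p_fdr`).
#' @export
adjusted_group_test <- function(variable, groups, covariates = NULL) {
  groups <- factor(groups)
  ok <- !is.na(variable) & !is.na(groups)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  variable <- variable[ok]
  groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L || min(table(groups)) < 3L)
    stop_input("need >= 2 groups with >= 3 subjects each")
  if (stats::sd(variable) == 0) stop_input("constant variable")
  y <- variable
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)[ok, , drop = FALSE]
    y <- stats::residuals(stats::lm(variable ~ ., data = cv))
  }
  kw <- stats::kruskal.test(y, groups)
  ## Dunn's test on the pooled ranks
  r <- rank(y)
  N <- length(y)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  mr <- tapply(r, groups, mean)
  ns <- table(groups)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  z <- apply(pairs, 2L, function(pr) {
    (mr[[pr[1]]] - mr[[pr[2]]]) /
      sqrt(s2 * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  posthoc <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                        p_raw = p_raw, p_fdr = adjust_bh(p_raw),
                        stringsAsFactors = FALSE)
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, posthoc = posthoc)
}

#' Contingency-table test with small-sample fallback
#'
#' Pearson's chi-squared test of independence; for 2x2 tables with any
#' expected cell below 5 the two-sided Fisher exact test is used instead
#' (`method = "auto"`). The Fisher p-value is the standard two-sided sum of
#' table probabilities at or below the observed one; `midp = TRUE` gives the
#' less conservative mid-p variant (half weight on the observed table).
#'
#' @param tab contingency table (matrix or table of counts).
#' @param method `"auto"` (default), `"fisher"` or `"chisq"`.
#' @param midp use the mid-p correction for the Fisher branch.
#' @return list with `method`, `statistic` (NA for Fisher), `p_value`.
#' @export
categorical_test <- function(tab, method = c("auto", "fisher", "chisq"),
                             midp = FALSE) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_input("contingency table has an empty margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- method == "fisher" ||
    (method == "auto" && all(dim(tab) == c(2L, 2L)) && any(expected < 5))
  if (use_fisher) {
    if (!all(dim(tab) == c(2L, 2L))) stop_input("Fisher branch expects a 2x2 table")
    p <- stats::fisher.test(tab)$p.value
    if (midp) {
      rs <- rowSums(tab)
      cs <- colSums(tab)
      p <- p - 0.5 * stats::dhyper(tab[1, 1], cs[1], cs[2], rs[1])
    }
    return(list(method = "fisher", statistic = NA_real_, p_value = p))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(method = "chisq", statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Covariate-adjusted Spearman correlations of stage with clinical variables
#'
#' Residualizes both the stage and each variable on the covariates (ordinary
#' least squares), computes Spearman's rho on the residual pairs, and
#' adjusts the p-values by Benjamini-Hochberg across the variable family.
#'
#' @param stage numeric stage vector.
#' @param variables data.frame of clinical variables (one test per column).
#' @param covariates optional data.frame of adjustment covariates.
#' @param min_n minimum paired observations per variable (default 10).
#' @return data.frame: `variable`, `n`, `rho`, `p_raw`, `p_fdr` (rows with
#'   constant input get `NA` with a warning).
#' @export
stage_correlations <- function(stage, variables, covariates = NULL, min_n = 10L) {
  variables <- as.data.frame(variables)
  res <- lapply(names(variables), function(v) {
    x <- stage
    y <- variables[[v]]
    ok <- !is.na(x) & !is.na(y)
    if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
    if (sum(ok) < min_n)
      stop_input("fewer than %d paired observations for '%s'", min_n, v)
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("constant input for '%s'; returning NA", v), call. = FALSE)
      return(data.frame(variable = v, n = sum(ok), rho = NA_real_,
                        p_raw = NA_real_, stringsAsFactors = FALSE))
    }
    if (!is.null(covariates)) {
      cv <- as.data.frame(covariates)[ok, , drop = FALSE]
      x <- stats::residuals(stats::lm(x ~ ., data = cv))
      y <- stats::residuals(stats::lm(y ~ ., data = cv))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    data.frame(variable = v, n = sum(ok), rho = unname(ct$estimate),
               p_raw = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_fdr[ok] <- adjust_bh(out$p_raw[ok])
  out
}

## term p-values of a coxph fit via likelihood-ratio drop1
cox_term_p <- function(fit, data) {
  dr <- stats::drop1(fit, test = "Chisq")
  p <- dr[["Pr(>Chi)"]]
  names(p) <- rownames(dr)
  p[!is.na(p)]
}

## tidy HR table from a coxph fit
cox_hr_table <- function(fit) {
  s <- summary(fit)
  ci <- s$conf.int
  data.frame(
    term = rownames(s$coefficients),
    hr = unname(s$coefficients[, "exp(coef)"]),
    ci_low = unname(ci[, "lower .95"]),
    ci_high = unname(ci[, "upper .95"]),
    p = unname(s$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
}

#' Univariate, multivariate and backward-selected Cox models
#'
#' Fits a univariate Cox proportional-hazards model per covariate, a full
#' multivariate model, and a stepwise-backward model that repeatedly drops
#' the least significant term (likelihood-ratio p) until every retained term
#' has p < `keep_p` (default 0.10). Non-convergence or separation is flagged
#' per covariate rather than silently ignored.
#'
#' @param records data.frame with columns `time` (> 0) and `event` (0/1)
#'   plus the covariates.
#' @param covariates character vector of covariate column names.
#' @param keep_p backward-selection retention threshold.
#' @return list with `univariate`, `multivariate`, `final` (HR tables with
#'   95% CI and p), `final_terms`, and `flags` (per-covariate notes).
#' @export
cox_models <- function(records, covariates, keep_p = 0.10) {
  if (!all(c("time", "event") %in% names(records)))
    stop_input("records need 'time' and 'event' columns")
  if (any(records$time <= 0, na.rm = TRUE)) stop_input("times must be positive")
  if (sum(records$event, na.rm = TRUE) < 10L)
    stop_input("need >= 10 events")
  flags <- character(0)
  for (v in covariates) {
    x <- records[[v]]
    if ((is.numeric(x) && stats::sd(x, na.rm = TRUE) == 0) ||
        (!is.numeric(x) && length(unique(stats::na.omit(x))) < 2L))
      stop_input("zero-variance covariate '%s'", v)
  }
  surv <- survival::Surv(records$time, records$event)
  safe_fit <- function(fml) {
    tryCatch(survival::coxph(fml, data = records),
             warning = function(w) {
               fit <- suppressWarnings(survival::coxph(fml, data = records))
               attr(fit, "flag") <- conditionMessage(w)
               fit
             },
             error = function(e) NULL)
  }
  uni <- do.call(rbind, lapply(covariates, function(v) {
    fit <- safe_fit(stats::as.formula(paste("surv ~", v)))
    if (is.null(fit)) {
      flags <<- c(flags, sprintf("%s: univariate fit failed", v))
      return(NULL)
    }
    if (!is.null(attr(fit, "flag")))
      flags <<- c(flags, sprintf("%s: %s", v, attr(fit, "flag")))
    cox_hr_table(fit)
  }))
  full_fml <- stats::as.formula(paste("surv ~", paste(covariates, collapse = " + ")))
  full <- safe_fit(full_fml)
  if (is.null(full)) stop_input("multivariate Cox model failed to converge")
  if (!is.null(attr(full, "flag")))
    flags <- c(flags, sprintf("multivariate: %s", attr(full, "flag")))
  ## backward elimination on term-level LRT p-values
  terms_now <- covariates
  fit_now <- full
  repeat {
    p <- cox_term_p(fit_now, records)
    if (!length(p) || max(p) < keep_p || length(terms_now) == 1L) break
    drop_term <- names(p)[which.max(p)]
    terms_now <- setdiff(terms_now, drop_term)
    if (!length(terms_now)) break
    fit_now <- safe_fit(stats::as.formula(
      paste("surv ~", paste(terms_now, collapse = " + "))))
    if (is.null(fit_now)) {
      flags <- c(flags, "backward step failed; keeping previous model")
      terms_now <- c(terms_now, drop_term)
      fit_now <- safe_fit(stats::as.formula(
        paste("surv ~", paste(terms_now, collapse = " + "))))
      break
    }
  }
  list(univariate = uni, multivariate = cox_hr_table(full),
       final = if (length(terms_now)) cox_hr_table(fit_now) else NULL,
       final_terms = terms_now, flags = flags)
}

#' One-versus-all subtype contrasts adjusted for stage
#'
#' Per biomarker/region, fits the linear model
#' `z ~ is_subtype + weighted_stage` and reports the t statistic (and p) of
#' the subtype indicator: how one subtype differs from all others at a
#' comparable stage.
#'
#' @param Z z-score data.frame (subjects x regions).
#' @param assignments `assignment_table` aligned with `Z` (non-NA subjects
#'   are used).
#' @param subtype subtype label to contrast (e.g. `"S1"`).
#' @param regions region columns (default: all numeric z columns).
#' @return data.frame: `region`, `t`, `p`.
#' @export
one_vs_all_contrast <- function(Z, assignments, subtype, regions = NULL) {
  keep <- !assignments$na_flag
  sub <- assignments$ml_subtype[keep]
  if (length(unique(sub)) < 2L) stop_input("need >= 2 subtypes for a contrast")
  if (min(table(sub)) < 5L) stop_input("need >= 5 subjects per subtype")
  if (!subtype %in% sub) stop_input("subtype '%s' not present", subtype)
  Zk <- as.data.frame(Z)[keep, , drop = FALSE]
  if (is.null(regions))
    regions <- names(Zk)[vapply(Zk, is.numeric, TRUE)]
  stage <- assignments$weighted_stage[keep]
  is_sub <- as.numeric(sub == subtype)
  out <- lapply(regions, function(rg) {
    fit <- stats::lm(Zk[[rg]] ~ is_sub + stage)
    sm <- summary(fit)$coefficients
    data.frame(region = rg, t = sm["is_sub", "t value"],
               p = sm["is_sub", "Pr(>|t|)"], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Treatment-response rates by subtype with pairwise Fisher tests
#'
#' A responder has no relapse during follow-up (relapse endpoint) or no
#' EDSS worsening per [flag_edss_progression()] (EDSS endpoint). Reports
#' responders/total and percentage per subtype and all pairwise two-sided
#' Fisher exact tests with Benjamini-Hochberg adjustment per endpoint.
#'
#' @param clinical clinical table with `subject_id`, `followup_relapses`,
#'   `edss`, `followup_edss` and optionally `treatment`.
#' @param assignments `assignment_table` with `subject_id`, `ml_subtype`.
#' @param treated_only restrict to `treatment == "DMT"` rows when a
#'   treatment column is present (default TRUE).
#' @return list with `rates` (data.frame: `subtype`, `endpoint`,
#'   `responders`, `total`, `percent`) and `tests` (pairwise Fisher raw/FDR
#'   p per endpoint). Empty subtypes are omitted with a warning.
#' @export
dmt_response <- function(clinical, assignments, treated_only = TRUE) {
  d <- merge(clinical, assignments[, c("subject_id", "ml_subtype")],
             by = "subject_id")
  if (treated_only && "treatment" %in% names(d)) d <- d[d$treatment == "DMT", ]
  d <- d[!is.na(d$followup_edss) | !is.na(d$followup_relapses), ]
  if (!nrow(d)) stop_input("no treated subjects with follow-up")
  d$resp_relapse <- d$followup_relapses == 0
  d$resp_edss <- !flag_edss_progression(d$edss, d$followup_edss)
  subs <- sort(unique(d$ml_subtype))
  empty <- setdiff(unique(assignments$ml_subtype), subs)
  if (length(empty))
    warning(sprintf("subtypes without treated follow-up omitted: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  rates <- do.call(rbind, lapply(c("resp_relapse", "resp_edss"), function(ep) {
    do.call(rbind, lapply(subs, function(s) {
      r <- d[[ep]][d$ml_subtype == s]
      r <- r[!is.na(r)]
      data.frame(subtype = s,
                 endpoint = if (ep == "resp_relapse") "relapse" else "edss",
                 responders = sum(r), total = length(r),
                 percent = 100 * sum(r) / length(r), stringsAsFactors = FALSE)
    }))
  }))
  if (length(subs) < 2L) return(list(rates = rates, tests = NULL))
  tests <- do.call(rbind, lapply(c("relapse", "edss"), function(ep) {
    col <- if (ep == "relapse") "resp_relapse" else "resp_edss"
    prs <- utils::combn(subs, 2)
    tb <- lapply(seq_len(ncol(prs)), function(j) {
      a <- d[[col]][d$ml_subtype == prs[1, j]]
      b <- d[[col]][d$ml_subtype == prs[2, j]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      m <- matrix(c(sum(a), length(a) - sum(a), sum(b), length(b) - sum(b)),
                  2, byrow = TRUE)
      data.frame(endpoint = ep, group1 = prs[1, j], group2 = prs[2, j],
                 p_raw = stats::fisher.test(m)$p.value, stringsAsFactors = FALSE)
    })
    tb <- do.call(rbind, tb)
    tb$p_fdr <- adjust_bh(tb$p_raw)
    tb
  }))
  list(rates = rates, tests = tests)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a validated wrapper over
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values (monotone in rank, each >= raw, all <= 1).
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_input("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
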