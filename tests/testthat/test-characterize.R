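test_that("EDSS progression rule follows the baseline-dependent thresholds", {
  expect_true(flag_edss_progression(3.0, 4.0))
  expect_true(flag_edss_progression(6.0, 6.5))
  expect_false(flag_edss_progression(3.0, 3.5))
  expect_false(flag_edss_progression(5.5, 6.0)) # baseline <= 5.5 needs +1.0
  expect_true(flag_edss_progression(5.5, 6.5))
  expect_true(is.na(flag_edss_progression(3.0, NA)))
  expect_error(flag_edss_progression(3.2, 4.0), "grid")
  ## vectorized
  expect_equal(flag_edss_progression(c(2, 6), c(3, 6.5)), c(TRUE, TRUE))
})

test_that("secondary-progressive conversion needs sustained relapse-free EDSS >= 4", {
  rec <- function(time, edss, relapse = 0) {
    data.frame(time = time, edss = edss, relapse = relapse)
  }
  ## progression to 4.0 sustained 8 months, no relapse: conversion
  expect_true(flag_spms_conversion(rec(c(0, 2, 10), c(3.0, 4.0, 4.0))))
  ## progression to 3.5 sustained 12 months: no conversion (EDSS < 4)
  expect_false(flag_spms_conversion(rec(c(0, 2, 14), c(2.0, 3.5, 3.5))))
  ## relapse inside the 6-month sustaining window: no conversion
  expect_false(flag_spms_conversion(
    rec(c(0, 2, 5, 10), c(3.0, 4.0, 4.0, 4.0), relapse = c(0, 0, 1, 0))))
  ## not sustained: EDSS falls back before 6 months have passed
  expect_false(flag_spms_conversion(rec(c(0, 2, 5, 10), c(3.0, 4.0, 3.0, 3.0))))
  ## insufficient follow-up
  expect_true(is.na(flag_spms_conversion(rec(c(0, 4), c(3.0, 4.0)))))
})

test_that("Kruskal-Wallis H equals the textbook rank statistic", {
  set.seed(81)
  y <- c(1.2, 3.4, 2.2, 5.6, 4.4, 7.1, 6.5, 8.0, 9.3)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  res <- adjusted_group_test(y, g)
  ## textbook H with no ties
  r <- rank(y)
  N <- length(y)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, function(x) length(x) * mean(x)^2)) -
    3 * (N + 1)
  expect_equal(res$statistic, H, tolerance = 1e-10)
  expect_equal(nrow(res$posthoc), 3) # all pairs
  expect_error(adjusted_group_test(rep(1, 9), g), "constant")
})

test_that("covariate-shifted groups are recovered after residualization", {
  set.seed(82)
  n <- 240
  g <- factor(rep(c("a", "b", "c"), each = n / 3))
  age <- runif(n, 20, 60)
  y <- 0.4 * age + rnorm(n) + 2 * (g == "c") # group c shifted by +2 SD
  res <- adjusted_group_test(y, g, covariates = data.frame(age = age))
  expect_lt(res$p_value, 0.001)
  sig <- res$posthoc$p_fdr < 0.05
  involves_c <- res$posthoc$group1 == "c" | res$posthoc$group2 == "c"
  expect_true(all(sig[involves_c]))
  expect_false(any(sig[!involves_c]))
})

test_that("contingency tests switch to Fisher and match printed arithmetic", {
  ## perfectly proportional table: statistic 0, p = 1
  prop_tab <- matrix(c(20, 40, 10, 20), 2)
  res <- categorical_test(prop_tab)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  ## the responder table 11/14 vs 10/26: standard two-sided Fisher equals
  ## exhaustive hypergeometric enumeration; the mid-p variant reproduces the
  ## printed 0.015
  tab <- matrix(c(11, 3, 10, 16), 2, byrow = TRUE)
  res2 <- categorical_test(tab, method = "fisher")
  expect_equal(res2$method, "fisher")
  enum_fisher <- function(tab) {
    rs <- rowSums(tab); cs <- colSums(tab)
    p_obs <- dhyper(tab[1, 1], cs[1], cs[2], rs[1])
    xs <- max(0, rs[1] - cs[2]):min(cs[1], rs[1])
    ps <- dhyper(xs, cs[1], cs[2], rs[1])
    sum(ps[ps <= p_obs * (1 + 1e-7)])
  }
  expect_equal(res2$p_value, enum_fisher(tab), tolerance = 1e-12)
  resmp <- categorical_test(tab, method = "fisher", midp = TRUE)
  expect_equal(round(resmp$p_value, 3), 0.015)
  ## small expected cells trigger the Fisher fallback automatically
  small_tab <- matrix(c(1, 9, 9, 2), 2, byrow = TRUE)
  expect_equal(categorical_test(small_tab)$method, "fisher")
  expect_error(categorical_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("partial Spearman correlations match the rank formula and recover links", {
  ## 6-point toy vector against the hand rank formula (no ties)
  x <- c(10, 20, 30, 40, 50, 60)
  y <- c(1.2, 0.8, 2.5, 2.1, 3.9, 3.0)
  res <- stage_correlations(x, data.frame(v = y), min_n = 6)
  d <- rank(x) - rank(y)
  rho_hand <- 1 - 6 * sum(d^2) / (6 * (6^2 - 1))
  expect_equal(res$rho, rho_hand, tolerance = 1e-10)
  ## monotone function of stage: rho = 1
  res1 <- stage_correlations(1:20, data.frame(v = (1:20)^3), min_n = 10)
  expect_equal(res1$rho, 1)
  ## known partial association survives covariate adjustment
  set.seed(83)
  n <- 400
  age <- runif(n, 20, 60)
  stage <- 0.3 * age + rnorm(n)
  edss <- 0.5 * stage + 0.2 * age + rnorm(n)
  res2 <- stage_correlations(stage, data.frame(edss = edss),
                             covariates = data.frame(age = age))
  expect_gt(res2$rho, 0.25)
  expect_lt(res2$p_raw, 1e-4)
  ## constant input yields NA with a warning
  expect_warning(
    out <- stage_correlations(1:20, data.frame(v = rep(2, 20)), min_n = 10),
    "constant")
  expect_true(is.na(out$rho))
})

test_that("Cox models estimate a known hazard ratio and drop noise covariates", {
  set.seed(84)
  n <- 1000
  grp <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.05 * 2^grp)
  cens <- runif(n, 5, 40)
  rec <- data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens),
                    grp = grp)
  res <- cox_models(rec, "grp")
  hr <- res$univariate$hr[res$univariate$term == "grp"]
  expect_gt(hr, 1.7)
  expect_lt(hr, 2.4)
  ## null covariate: CI contains 1
  set.seed(4242)
  rec$null_cov <- rnorm(n)
  res2 <- cox_models(rec, "null_cov")
  expect_true(res2$univariate$ci_low[1] < 1 && res2$univariate$ci_high[1] > 1)
  ## stepwise keeps the true predictor, mostly drops pure noise
  keep_true <- 0
  noise_kept <- 0
  reps <- 30
  for (r in 1:reps) {
    m <- 300
    x1 <- rbinom(m, 1, 0.5)
    noise <- matrix(rnorm(m * 3), m, 3)
    tv <- rexp(m, 0.05 * exp(log(2) * x1))
    cn <- runif(m, 5, 40)
    d <- data.frame(time = pmin(tv, cn), event = as.integer(tv <= cn),
                    x1 = x1, n1 = noise[, 1], n2 = noise[, 2], n3 = noise[, 3])
    sel <- cox_models(d, c("x1", "n1", "n2", "n3"))$final_terms
    keep_true <- keep_true + ("x1" %in% sel)
    noise_kept <- noise_kept + length(intersect(c("n1", "n2", "n3"), sel))
  }
  expect_gte(keep_true / reps, 0.8)
  expect_lte(noise_kept / (3 * reps), 0.3) # well under chance retention
  expect_error(cox_models(rec[rec$event == 0, ][1:20, ], "grp"), "10 events")
})

test_that("one-vs-all contrasts detect injected regional offsets and respect stage", {
  set.seed(85)
  n <- 200
  sub <- rep(c("S1", "S2"), each = n / 2)
  stage <- runif(n, 0, 10)
  z1 <- 0.3 * stage + rnorm(n) + 1.0 * (sub == "S1") # genuine offset
  z2 <- 0.3 * stage + rnorm(n)                       # stage-mediated only
  Z <- data.frame(r1 = z1, r2 = z2)
  a <- data.frame(subject_id = sprintf("s%03d", 1:n), na_flag = FALSE,
                  ml_subtype = sub, weighted_stage = stage,
                  stringsAsFactors = FALSE)
  res <- one_vs_all_contrast(Z, a, "S1")
  expect_gt(res$t[res$region == "r1"], 0)
  expect_lt(res$p[res$region == "r1"], 0.01)
  expect_lt(abs(res$t[res$region == "r2"]), 2.5)
  ## stage adjustment attenuates a purely stage-mediated difference
  stage2 <- ifelse(sub == "S1", runif(n, 5, 10), runif(n, 0, 5))
  z3 <- 0.5 * stage2 + rnorm(n)
  a2 <- a
  a2$weighted_stage <- stage2
  t_adj <- one_vs_all_contrast(data.frame(r = z3), a2, "S1")$t
  t_unadj <- summary(lm(z3 ~ I(sub == "S1")))$coefficients[2, "t value"]
  expect_lt(abs(t_adj), abs(t_unadj))
  expect_error(one_vs_all_contrast(Z, a[a$ml_subtype == "S1", ], "S1"),
               ">= 2 subtypes")
})

test_that("treatment response rates reproduce printed count arithmetic", {
  ## 14 treated NA-subtype subjects with 11 relapse-free; 60 treated S2 with
  ## 32 free of EDSS worsening
  clin <- data.frame(
    subject_id = sprintf("p%03d", 1:74),
    edss = 3.0,
    followup_edss = c(rep(3.0, 11), rep(4.5, 3), rep(3.0, 32), rep(4.5, 28)),
    followup_relapses = c(rep(0, 11), rep(2, 3), rep(1, 60)),
    treatment = "DMT",
    stringsAsFactors = FALSE
  )
  asg <- data.frame(subject_id = clin$subject_id,
                    ml_subtype = c(rep("NA", 14), rep("S2", 60)),
                    stringsAsFactors = FALSE)
  res <- dmt_response(clin, asg)
  r <- res$rates
  expect_equal(round(r$percent[r$subtype == "NA" & r$endpoint == "relapse"], 1),
               78.6) # 11/14
  expect_equal(round(r$percent[r$subtype == "S2" & r$endpoint == "edss"], 1),
               53.3) # 32/60
  ## all-responder groups: Fisher p = 1
  clin2 <- clin
  clin2$followup_relapses <- 0
  clin2$followup_edss <- clin2$edss
  res2 <- dmt_response(clin2, asg)
  expect_true(all(res2$tests$p_raw == 1))
})

test_that("Benjamini-Hochberg adjustment matches the brute-force step-up", {
  bh_brute <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  set.seed(86)
  for (r in 1:20) {
    p <- runif(sample(1:12, 1))
    a <- adjust_bh(p)
    expect_equal(a, bh_brute(p), tolerance = 1e-12)
    expect_true(all(a >= p - 1e-12) && all(a <= 1))
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})
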