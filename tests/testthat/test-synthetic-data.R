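test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_hc = 40, n_patients = 60, seed = 11)
  expect_identical(generate_hc_cohort(cfg), generate_hc_cohort(cfg))
  p1 <- generate_patient_cohort(cfg)
  p2 <- generate_patient_cohort(cfg)
  expect_identical(p1, p2)
  expect_identical(generate_clinical(p1$truth, cfg),
                   generate_clinical(p2$truth, cfg))
  ## different seed -> different draws
  cfg2 <- sim_config(n_hc = 40, n_patients = 60, seed = 12,
                     orderings = cfg$orderings)
  expect_false(identical(generate_hc_cohort(cfg2), generate_hc_cohort(cfg)))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(noise_sd = -1), "nonnegative")
  expect_error(sim_config(n_hc = 0), "n_hc")
  expect_error(sim_config(fractions = c(0.7, 0.4)), "sum to 1")
  expect_error(sim_config(n_subtypes = 2, fractions = c(1)), "length")
  expect_error(sim_config(clinical_model = list(hazard = -0.1)), "nonnegative")
  ## ordering violating the within-biomarker threshold order
  es <- event_set(paste0("b", 1:8))
  bad <- seq_len(es$E)
  bad[1:2] <- bad[2:1]
  expect_error(sim_config(orderings = list(bad), n_subtypes = 1), "invalid ordering")
})

test_that("batch offsets appear in HC volume means; zero noise hits baselines", {
  cfg <- sim_config(n_hc = 10000, n_patients = 10,
                    biomarkers = c("cortical_gm", "mucca"),
                    batch_offsets = c(A = 0, B = 5),
                    age_slope = 0, sex_offset = 0, tiv_slope = 0,
                    noise_sd = 1, seed = 21)
  hc <- generate_hc_cohort(cfg)
  d <- mean(hc$cortical_gm[hc$scanner == "B"]) -
    mean(hc$cortical_gm[hc$scanner == "A"])
  expect_lt(abs(d - 5), 0.1) # MC error ~ sqrt(2/5000) = 0.02
  ## degenerate noise: volumes equal the baseline constant exactly
  cfg0 <- sim_config(n_hc = 25, n_patients = 5, biomarkers = c("cortical_gm"),
                     batch_offsets = c(A = 0), age_slope = 0, sex_offset = 0,
                     tiv_slope = 0, noise_sd = 0, seed = 3)
  hc0 <- generate_hc_cohort(cfg0)
  expect_true(all(hc0$cortical_gm == hc0$cortical_gm[1]))
})

test_that("patient mixing fractions and stage-conditional means match the model", {
  cfg <- sim_config(n_hc = 10, n_patients = 20000, n_subtypes = 2,
                    fractions = c(0.6, 0.4), seed = 31)
  pc <- generate_patient_cohort(cfg)
  ## binomial MC bound on empirical fractions
  expect_lt(abs(mean(pc$truth$subtype == 1) - 0.6), 0.02)
  ## per-stage empirical mean z of a biomarker matches the trajectory within
  ## 3 SE (invert the volume scale back to z via the config noise SD)
  es <- cfg$event_set
  b <- "cortical_gm"
  sexM <- as.numeric(pc$truth$sex == "M")
  hc_pred <- cfg$baselines[[b]] +
    cfg$age_slope[[b]] * (pc$truth$age - 40) +
    cfg$sex_offset[[b]] * sexM +
    cfg$tiv_slope[[b]] * (pc$truth$tiv - 1450) +
    cfg$batch_offsets[as.character(pc$truth$scanner)]
  z_emp <- (hc_pred - pc$biomarkers[[b]]) / cfg$noise_sd[[b]]
  for (k in c(2L, 10L, 20L)) {
    sel <- pc$truth$stage == k & pc$truth$subtype == 1
    g <- trajectory(es, cfg$orderings[[1]], b, k)
    se <- 1 / sqrt(sum(sel)) # z-noise has unit SD by construction
    expect_lt(abs(mean(z_emp[sel]) - g), 3 * se)
  }
  ## stage-0 patients have mean z about 0 under perfect adjustment
  sel0 <- pc$truth$stage == 0
  expect_lt(abs(mean(z_emp[sel0])), 3 / sqrt(sum(sel0)))
})

test_that("clinical outcomes track stage and subtype as configured", {
  cfg <- sim_config(n_hc = 10, n_patients = 2000, n_subtypes = 2,
                    fractions = c(0.5, 0.5),
                    clinical_model = list(hazard = c(0.01, 0.02),
                                          admin_censor = 10),
                    seed = 41)
  pc <- generate_patient_cohort(cfg)
  cl <- generate_clinical(pc$truth, cfg)
  ## EDSS on the half-point grid within [0, 10]
  expect_true(all(cl$edss * 2 == round(cl$edss * 2)))
  expect_true(all(cl$edss >= 0 & cl$edss <= 10))
  ## exponential closed form: event-rate ratio ~ hazard ratio at a short
  ## horizon (h * t small)
  r1 <- mean(cl$progression_event[pc$truth$subtype == 1])
  r2 <- mean(cl$progression_event[pc$truth$subtype == 2])
  true_ratio <- (1 - exp(-0.02 * 10)) / (1 - exp(-0.01 * 10))
  expect_equal(r2 / r1, true_ratio, tolerance = 0.25)
  ## follow-up EDSS consistent with the progression flag
  prog <- flag_edss_progression(cl$edss, cl$followup_edss)
  expect_true(all(prog[cl$progression_event == 1]))
  expect_false(any(prog[cl$progression_event == 0]))
})

test_that("null clinical couplings yield null associations", {
  cfg <- sim_config(n_hc = 10, n_patients = 3000, n_subtypes = 2,
                    fractions = c(0.5, 0.5),
                    clinical_model = list(edss_stage_slope = 0,
                                          hazard = c(0.02, 0.02),
                                          admin_censor = 24),
                    seed = 51)
  pc <- generate_patient_cohort(cfg)
  cl <- generate_clinical(pc$truth, cfg)
  ## equal hazards: event proportions equal within MC error
  p1 <- mean(cl$progression_event[pc$truth$subtype == 1])
  p2 <- mean(cl$progression_event[pc$truth$subtype == 2])
  expect_lt(abs(p1 - p2), 3 * sqrt(2 * 0.4 * 0.6 / 1500))
  ## zero stage-EDSS slope: Spearman about 0
  rho <- cor(pc$truth$stage, cl$edss, method = "spearman")
  expect_lt(abs(rho), 3 / sqrt(nrow(cl)))
})

test_that("follow-up stages never regress and shift z upward when advanced", {
  cfg <- sim_config(n_hc = 10, n_patients = 400, n_subtypes = 1,
                    fractions = 1, seed = 61)
  pc <- generate_patient_cohort(cfg)
  fu <- generate_followup(pc$truth, cfg, increment_mean = 3)
  expect_true(all(fu$truth$stage >= pc$truth$stage))
  expect_true(all(fu$truth$subtype == pc$truth$subtype))
  expect_true(all(fu$biomarkers$visit == "followup"))
  ## degenerate increment: stages unchanged, volumes redrawn around the same
  ## expected values
  fu0 <- generate_followup(pc$truth, cfg, increment_mean = 0)
  expect_identical(fu0$truth$stage, pc$truth$stage)
  d <- mean(as.matrix(fu0$biomarkers[cfg$biomarkers])) -
    mean(as.matrix(pc$biomarkers[cfg$biomarkers]))
  expect_lt(abs(d), 0.5)
  ## a large advance pushes mean z strictly above baseline:
  ## volumes drop, so baseline-minus-followup volume means are positive
  fu10 <- generate_followup(pc$truth[pc$truth$stage <= 10, ], cfg,
                            increment_mean = 10)
  base_keep <- pc$biomarkers[pc$truth$stage <= 10, ]
  expect_gt(mean(as.matrix(base_keep[cfg$biomarkers])) -
              mean(as.matrix(fu10$biomarkers[cfg$biomarkers])), 0)
})
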