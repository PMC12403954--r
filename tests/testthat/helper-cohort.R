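## Shared fixtures: end-to-end synthetic cohorts and small z datasets.

## Full chain: simulate volumes -> adjust -> match -> z-score.
## Stages are uniform on 1..E by default (every patient carries signal);
## pass stage0 = TRUE for the full 0..E grid.
make_recovery_cohort <- function(seed, n_patients = 600L, n_hc = 900L,
                                 n_biomarkers = 8L, fractions = c(0.6, 0.4),
                                 stage0 = FALSE) {
  bm <- paste0("bm", seq_len(n_biomarkers))
  E <- 3L * n_biomarkers
  sd_stage <- if (stage0) rep(1 / (E + 1), E + 1L) else c(0, rep(1 / E, E))
  cfg <- sim_config(n_hc = n_hc, n_patients = n_patients, biomarkers = bm,
                    n_subtypes = length(fractions), fractions = fractions,
                    stage_distribution = sd_stage, seed = seed)
  hc <- generate_hc_cohort(cfg)
  pc <- generate_patient_cohort(cfg)
  adj <- adjust_batch_covariates(rbind(hc, pc$biomarkers))
  hcs <- adj[adj$group == "HC", ]
  pats <- adj[adj$group != "HC", ]
  pairs <- match_controls(pats, hcs, seed = seed)
  matched <- hcs[match(pairs$hc_id, hcs$subject_id), ]
  Z <- compute_zscores(pats, matched)
  list(cfg = cfg, es = cfg$event_set, Z = Z, truth = pc$truth,
       hc = hc, patients = pc$biomarkers, adjusted = adj)
}

## Direct z-space sample from known orderings (model-level fixtures).
make_z_sample <- function(es, orderings, fractions, n, seed,
                          stages = NULL, noise_sd = 1) {
  set.seed(seed)
  sub <- sample.int(length(orderings), n, replace = TRUE, prob = fractions)
  st <- if (is.null(stages)) sample(0:es$E, n, replace = TRUE) else
    sample(stages, n, replace = TRUE)
  G <- lapply(orderings, function(o) {
    vapply(es$biomarkers, function(b) trajectory(es, o, b, 0:es$E),
           numeric(es$E + 1L))
  })
  Z <- t(vapply(seq_len(n), function(i)
    G[[sub[i]]][st[i] + 1L, ] + stats::rnorm(length(es$biomarkers), 0, noise_sd),
    numeric(length(es$biomarkers))))
  colnames(Z) <- es$biomarkers
  list(Z = Z, subtype = sub, stage = st)
}

## Map fitted subtype labels to ground-truth labels by best Kendall agreement
## of the orderings (C = 2 only).
map_subtypes_2 <- function(models, truth_orderings) {
  tm <- matrix(c(
    ordering_kendall(models[[1]]$ordering, truth_orderings[[1]]),
    ordering_kendall(models[[1]]$ordering, truth_orderings[[2]]),
    ordering_kendall(models[[2]]$ordering, truth_orderings[[1]]),
    ordering_kendall(models[[2]]$ordering, truth_orderings[[2]])
  ), 2, byrow = TRUE)
  if (tm[1, 1] + tm[2, 2] >= tm[1, 2] + tm[2, 1]) {
    list(map = c(1L, 2L), taus = c(tm[1, 1], tm[2, 2]))
  } else {
    list(map = c(2L, 1L), taus = c(tm[1, 2], tm[2, 1]))
  }
}

## accuracy of subtype assignment against truth among subjects assigned to a
## subtype (NA rows excluded)
assignment_accuracy <- function(assignments, truth_subtype, map) {
  fitted_idx <- suppressWarnings(as.integer(sub("S", "", assignments$ml_subtype)))
  ok <- !is.na(fitted_idx)
  mean(map[fitted_idx[ok]] == truth_subtype[ok])
}
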