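test_that("dataset mixture log-likelihood reduces and enumerates correctly", {
  set.seed(23)
  es <- event_set(c("a", "b"), z_levels = c(1, 2), z_max = 4)
  o1 <- random_ordering(es)
  o2 <- random_ordering(es)
  Z <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, es$biomarkers))
  ## C = 1 reduces to the sum of subject marginals
  m1 <- list(list(ordering = o1, fraction = 1))
  expect_equal(loglik_dataset(Z, es, m1),
               sum(vapply(1:3, function(i) subject_marginal(Z[i, ], es, o1),
                          numeric(1))), tolerance = 1e-12)
  ## duplicated subtype at split fractions changes nothing
  m2 <- list(list(ordering = o1, fraction = 0.5),
             list(ordering = o1, fraction = 0.5))
  expect_equal(loglik_dataset(Z, es, m2), loglik_dataset(Z, es, m1),
               tolerance = 1e-12)
  ## subtype label permutation leaves the likelihood unchanged
  mix <- list(list(ordering = o1, fraction = 0.3),
              list(ordering = o2, fraction = 0.7))
  expect_equal(loglik_dataset(Z, es, mix), loglik_dataset(Z, es, rev(mix)),
               tolerance = 1e-12)
  ## brute force over every (subtype, stage) cell on the tiny instance
  brute <- sum(vapply(1:3, function(i) {
    log(0.3 * mean(vapply(0:es$E, function(k)
      stage_likelihood(Z[i, ], es, o1, k, log = FALSE), numeric(1))) +
        0.7 * mean(vapply(0:es$E, function(k)
          stage_likelihood(Z[i, ], es, o2, k, log = FALSE), numeric(1))))
  }, numeric(1)))
  expect_equal(loglik_dataset(Z, es, mix), brute, tolerance = 1e-10)
  expect_error(loglik_dataset(Z[0, ], es, m1), "empty")
  expect_error(loglik_dataset(Z, es, list(list(ordering = o1, fraction = 0.4))),
               "sum to 1")
})

test_that("single-subtype fit recovers a planted ordering", {
  es <- event_set(c("a", "b", "c", "d", "e"), z_levels = c(1, 2, 3), z_max = 5)
  truth <- random_ordering(es, seed = 41)
  sim <- make_z_sample(es, list(truth), 1, n = 500, seed = 42)
  fits <- lapply(1:5, function(s)
    fit_fixed_C(sim$Z, es, 1, n_starts = 6, mcmc_iters = 0, seed = s))
  taus <- vapply(fits, function(f) ordering_kendall(f[[1]]$ordering, truth),
                 numeric(1))
  expect_gte(mean(taus), 0.9)
  expect_error(fit_fixed_C(sim$Z, es, es$E + 1L, seed = 1), "exceeds")
})

test_that("EM trace is nondecreasing and the fit is seed-reproducible", {
  es <- event_set(c("a", "b"), z_levels = c(1, 2, 3), z_max = 5)
  sim <- make_z_sample(es, list(random_ordering(es, seed = 1),
                                random_ordering(es, seed = 2)),
                       c(0.5, 0.5), n = 150, seed = 3)
  f1 <- fit_fixed_C(sim$Z, es, 2, n_starts = 4, mcmc_iters = 500, seed = 9)
  tr <- attr(f1, "loglik_trace")
  expect_true(all(diff(tr) >= -1e-9))
  f2 <- fit_fixed_C(sim$Z, es, 2, n_starts = 4, mcmc_iters = 500, seed = 9)
  expect_identical(lapply(f1, `[[`, "ordering"), lapply(f2, `[[`, "ordering"))
  expect_identical(vapply(f1, `[[`, 1.0, "fraction"),
                   vapply(f2, `[[`, 1.0, "fraction"))
})

test_that("every MCMC sample respects the within-biomarker threshold order", {
  es <- event_set(c("a", "b"), z_levels = c(1, 2, 3), z_max = 5)
  sim <- make_z_sample(es, list(random_ordering(es, seed = 5)), 1,
                       n = 120, seed = 6)
  f <- fit_fixed_C(sim$Z, es, 1, n_starts = 3, mcmc_iters = 2000, seed = 7)
  smp <- f[[1]]$mcmc_samples
  expect_gt(nrow(smp), 100)
  ok <- apply(smp, 1L, function(o) is_valid_ordering(es, as.integer(o)))
  expect_true(all(ok))
  ## positional density rows are event distributions over positions
  pd <- f[[1]]$positional_density
  expect_equal(unname(rowSums(pd)), rep(1, es$E), tolerance = 1e-12)
})

test_that("fraction recovery on a two-subtype mixture", {
  es <- event_set(paste0("b", 1:4), z_levels = c(1, 2, 3), z_max = 5)
  o1 <- random_ordering(es, seed = 11)
  o2 <- random_ordering(es, seed = 12)
  sim <- make_z_sample(es, list(o1, o2), c(0.6, 0.4), n = 600, seed = 13,
                       stages = 1:es$E)
  f <- fit_fixed_C(sim$Z, es, 2, n_starts = 6, mcmc_iters = 0, seed = 14)
  mp <- map_subtypes_2(f, list(o1, o2))
  fr <- vapply(f, `[[`, 1.0, "fraction")
  expect_lt(max(abs(fr[order(mp$map)] - c(0.6, 0.4))), 0.10)
})

test_that("cross-validation partitions subjects once and is order-invariant", {
  es <- event_set(c("a", "b"), z_levels = c(1, 2), z_max = 4)
  sim <- make_z_sample(es, list(random_ordering(es, seed = 3)), 1,
                       n = 80, seed = 21)
  cv <- crossval_cvic(sim$Z, es, C_range = 1, folds = 5, n_starts = 2,
                      seed = 31, max_passes = 3)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_length(cv$folds, 80)
  expect_true(all(table(cv$folds) == 16))
  ## shuffling subject order with the same seed gives identical CVIC
  perm <- sample(80)
  cv2 <- crossval_cvic(sim$Z[perm, ], es, C_range = 1, folds = 5, n_starts = 2,
                       seed = 31, max_passes = 3)
  expect_equal(unname(cv$cvic), unname(cv2$cvic), tolerance = 1e-8)
  expect_error(crossval_cvic(sim$Z[1:4, ], es, folds = 5, seed = 1),
               "more folds")
})

test_that("CVIC selection applies the parsimony rule to worked examples", {
  expect_equal(select_C(c(100, 95, 94.5), parsimony_delta = 6), 2L)
  expect_equal(select_C(c(100, 80, 79), parsimony_delta = 6), 2L)
  expect_equal(select_C(c(50, 60, 70)), 1L)
  ## exact tie breaks toward the smaller C
  expect_equal(select_C(c(80, 80)), 1L)
  ## chained similarity walks all the way down
  expect_equal(select_C(c(90, 87, 84), parsimony_delta = 6), 1L)
  expect_error(select_C(numeric(0)), "nonempty")
})

test_that("fitted models serialize to JSON and back", {
  es <- event_set(c("a", "b"), z_levels = c(1, 2), z_max = 4)
  sim <- make_z_sample(es, list(random_ordering(es, seed = 8)), 1,
                       n = 60, seed = 9)
  fit <- fit_sustain(sim$Z, es, C_max = 2, folds = 5, n_starts = 2,
                     cv_n_starts = 2, mcmc_iters = 200, seed = 10)
  path <- tempfile(fileext = ".json")
  write_sustain_json(fit, path)
  back <- read_sustain_json(path)
  expect_equal(back$selected_C, fit$selected_C)
  expect_equal(back$cvic, fit$cvic)
  for (C in 1:2) {
    expect_identical(lapply(back$models[[C]], `[[`, "ordering"),
                     lapply(fit$models[[C]], `[[`, "ordering"))
  }
  expect_equal(loglik_dataset(sim$Z, es, back$selected_models),
               loglik_dataset(sim$Z, es, fit$selected_models))
})
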