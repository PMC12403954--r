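## ---- vectorized likelihood core ------------------------------------------
## All fitting code works on an n x B numeric matrix of atrophy z-scores with
## columns in event-set biomarker order. Log densities are computed from the
## cross-product decomposition sum((z-g)^2) = |z|^2 - 2 z.g + |g|^2 so that a
## whole stage grid (or a whole batch of candidate orderings) costs a single
## matrix multiply.

## coerce a ZScoreMatrix (matrix or data.frame) to the n x B matrix the
## likelihood code expects
as_z_matrix <- function(Z, es) {
  if (is.data.frame(Z)) {
    miss <- setdiff(es$biomarkers, names(Z))
    if (length(miss))
      stop_input("z-score table lacks biomarker columns: %s", paste(miss, collapse = ", "))
    Z <- as.matrix(Z[, es$biomarkers, drop = FALSE])
  }
  Z <- as.matrix(Z)
  if (ncol(Z) != length(es$biomarkers))
    stop_input("z matrix has %d columns; event set has %d biomarkers",
               ncol(Z), length(es$biomarkers))
  if (!is.null(colnames(Z)) && all(es$biomarkers %in% colnames(Z)))
    Z <- Z[, es$biomarkers, drop = FALSE]
  storage.mode(Z) <- "double"
  if (any(!is.finite(Z))) stop_input("z-scores must be finite")
  Z
}

## n x S matrix of log prod_b Normal(z_b; G[s,b], sigma_b) for the S stage
## rows of G
stage_logdens_matrix <- function(Z, es, G) {
  sigma <- es$sigma
  Zs <- sweep(Z, 2L, sigma, "/")
  Gs <- sweep(G, 2L, sigma, "/")
  const <- -0.5 * ncol(Z) * log(2 * pi) - sum(log(sigma))
  zz <- rowSums(Zs^2)
  gg <- rowSums(Gs^2)
  const - 0.5 * (outer(zz, gg, "+") - 2 * tcrossprod(Zs, Gs))
}

#' Gaussian stage likelihood of a z-score profile
#'
#' Density of an observed z-score row under the piecewise-linear model at a
#' given stage: the product over biomarkers of `Normal(z_b; g_b(k), sigma_b)`,
#' evaluated in log space.
#'
#' @param z_row numeric vector of z-scores (one per biomarker, in event-set
#'   order) or a named vector/1-row data.frame.
#' @param es an [event_set()].
#' @param ordering event ordering (see [is_valid_ordering()]).
#' @param k stage(s), numeric in `[0, E]`.
#' @param log return log density (default `TRUE`).
#' @return numeric vector of (log) densities, one per stage in `k`.
#' @export
stage_likelihood <- function(z_row, es, ordering, k, log = TRUE) {
  assert_ordering(es, ordering)
  z <- as_z_matrix(matrix(as.numeric(unlist(z_row)), nrow = 1L,
                          dimnames = list(NULL, names(unlist(z_row)))), es)
  if (any(!is.finite(k)) || any(k < 0 | k > es$E))
    stop_input("stage k must lie in [0, %d]", es$E)
  G <- vapply(es$biomarkers, function(b) trajectory(es, ordering, b, k),
              numeric(length(k)))
  if (length(k) == 1L) G <- matrix(G, nrow = 1L)
  ll <- drop(stage_logdens_matrix(z, es, G))
  if (log) ll else exp(ll)
}

#' Stage-marginal likelihood of a z-score profile
#'
#' Log of the subject marginal `P(x | S) = (E+1)^{-1} sum_{k=0}^{E} P(x | S, k)`
#' under a uniform prior over the integer stage grid (stage 0 included),
#' computed by log-sum-exp.
#'
#' @inheritParams stage_likelihood
#' @return log marginal likelihood (scalar).
#' @export
subject_marginal <- function(z_row, es, ordering) {
  assert_ordering(es, ordering)
  z <- as_z_matrix(matrix(as.numeric(unlist(z_row)), nrow = 1L,
                          dimnames = list(NULL, names(unlist(z_row)))), es)
  drop(subject_log_marginals(z, es, ordering))
}

## n-vector of log marginals under one ordering (uniform stage prior 0..E)
subject_log_marginals <- function(Z, es, ordering, G = NULL) {
  if (is.null(G)) G <- traj_matrix_fast(es, ordering)
  L <- stage_logdens_matrix(Z, es, G)
  row_logsumexp(L) - log(es$E + 1)
}

#' Posterior over stages for one subject
#'
#' Normalized posterior `P(k | x, S)` on the integer stage grid `0..E` under
#' the uniform stage prior.
#'
#' @inheritParams stage_likelihood
#' @return numeric vector of length `E + 1` summing to 1, named by stage.
#' @export
stage_posterior <- function(z_row, es, ordering) {
  ll <- stage_likelihood(z_row, es, ordering, 0:es$E, log = TRUE)
  p <- exp(ll - logsumexp(ll))
  names(p) <- 0:es$E
  p / sum(p)
}

## Batched evaluation: log marginal of every subject under every candidate
## ordering, via one stacked matrix multiply. Returns n x ncand matrix.
cand_log_marginals <- function(Z, es, orderings) {
  S <- es$E + 1L
  Gall <- do.call(rbind, lapply(orderings, function(o) traj_matrix_fast(es, o)))
  L <- stage_logdens_matrix(Z, es, Gall) # n x (S * ncand), blocks contiguous
  block_logsumexp(L, S) - log(S)
}

#' Mixture log-likelihood of a z-score dataset
#'
#' Total log-likelihood `sum_i log sum_c f_c P(x_i | S_c)` of a dataset
#' under a list of subtype models (orderings with mixture fractions).
#'
#' @param Z z-score matrix or data.frame (rows subjects, columns the event
#'   set's biomarkers).
#' @param es an [event_set()].
#' @param models list of subtype models, each a list with elements
#'   `ordering` and `fraction`; fractions must be nonnegative and sum to 1.
#' @return scalar log-likelihood.
#' @export
loglik_dataset <- function(Z, es, models) {
  Z <- as_z_matrix(Z, es)
  if (nrow(Z) == 0L) stop_input("empty dataset")
  if (length(models) < 1L) stop_input("need at least one subtype model")
  f <- vapply(models, function(m) m$fraction, numeric(1))
  if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
    stop_input("mixture fractions must be nonnegative and sum to 1")
  logM <- vapply(models, function(m) subject_log_marginals(Z, es, m$ordering),
                 numeric(nrow(Z)))
  logM <- matrix(logM, nrow = nrow(Z))
  sum(row_logsumexp(sweep(logM, 2L, log(f), "+")))
}
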