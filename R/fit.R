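## ---- model fitting: greedy ascent, EM, MCMC, cross-validation ------------

## All candidate reinsertions of the event at position p into every other
## position, keeping within-biomarker threshold order. Returns list of
## orderings (may include the original).
reinsertion_candidates <- function(es, ordering, p) {
  e <- ordering[p]
  rest <- ordering[-p]
  ## valid insertion slots form the contiguous range between the event's
  ## same-biomarker threshold neighbours
  lo <- 1L
  hi <- es$E
  if (es$prev_ev[e] > 0L) lo <- which(rest == es$prev_ev[e]) + 1L
  if (es$next_ev[e] > 0L) hi <- which(rest == es$next_ev[e])
  lapply(lo:hi, function(q) append(rest, e, after = q - 1L))
}

## One full greedy pass: for each event position, move the event to its best
## valid position under the (weighted) marginal log-likelihood. Weights w
## default to 1 (ordinary ML); with EM responsibilities this maximizes the
## expected complete-data log-likelihood for one subtype.
greedy_pass <- function(Z, es, ordering, w = NULL) {
  for (e in sample(seq_len(es$E))) {
    pos <- which(ordering == e) # event e's current position (ordering mutates)
    cands <- reinsertion_candidates(es, ordering, pos)
    M <- cand_log_marginals(Z, es, cands)
    obj <- if (is.null(w)) colSums(M) else colSums(w * M)
    ordering <- cands[[which.max(obj)]]
  }
  ordering
}

## Greedy ascent to a local optimum from one starting ordering.
greedy_ascent <- function(Z, es, ordering, w = NULL, max_passes = 10L, tol = 1e-9) {
  obj <- function(o) {
    m <- subject_log_marginals(Z, es, o)
    if (is.null(w)) sum(m) else sum(w * m)
  }
  cur <- obj(ordering)
  for (pass in seq_len(max_passes)) {
    ordering <- greedy_pass(Z, es, ordering, w)
    new <- obj(ordering)
    if (new - cur <= tol) break
    cur <- new
  }
  list(ordering = ordering, objective = cur)
}

## Multi-start single-subtype fit (weighted); returns best local optimum.
fit_single <- function(Z, es, w = NULL, n_starts = 10L, max_passes = 10L) {
  best <- NULL
  for (s in seq_len(n_starts)) {
    res <- greedy_ascent(Z, es, random_ordering(es), w = w, max_passes = max_passes)
    if (is.null(best) || res$objective > best$objective) best <- res
  }
  best
}

## E-step: n x C responsibility matrix and mixture log-likelihood
responsibilities <- function(logM, f) {
  A <- sweep(logM, 2L, log(f), "+")
  m <- apply(A, 1L, max)
  W <- exp(A - m)
  tot <- rowSums(W)
  list(R = W / tot, loglik = sum(m + log(tot)))
}

## Coordinate ascent / EM over fractions and orderings at fixed C.
## Each M-step updates fractions in closed form and improves each subtype's
## ordering with one weighted greedy pass (generalized EM).
em_refine <- function(Z, es, orderings, f, tol = 1e-6, max_iter = 100L) {
  C <- length(orderings)
  logM <- vapply(orderings, function(o) subject_log_marginals(Z, es, o),
                 numeric(nrow(Z)))
  logM <- matrix(logM, nrow = nrow(Z))
  est <- responsibilities(logM, f)
  trace <- est$loglik
  for (it in seq_len(max_iter)) {
    f <- pmax(colMeans(est$R), 1e-12)
    f <- f / sum(f)
    for (c in seq_len(C)) {
      orderings[[c]] <- greedy_pass(Z, es, orderings[[c]], w = est$R[, c])
      logM[, c] <- subject_log_marginals(Z, es, orderings[[c]])
    }
    est <- responsibilities(logM, f)
    trace <- c(trace, est$loglik)
    n <- length(trace)
    if (abs(trace[n] - trace[n - 1L]) < tol * abs(trace[n - 1L])) break
  }
  list(orderings = orderings, f = f, loglik = est$loglik, R = est$R,
       loglik_trace = trace)
}

## Metropolis MCMC over the joint orderings at fixed fractions.
## Proposal: choose a subtype uniformly, swap two uniformly chosen positions
## of its ordering; proposals violating within-biomarker order are rejected
## (the proposal kernel is symmetric, so this targets the posterior that is
## proportional to the mixture likelihood under a uniform prior on valid
## orderings).
mcmc_orderings <- function(Z, es, orderings, f, n_iter = 10000L, thin = NULL) {
  C <- length(orderings)
  E <- es$E
  n <- nrow(Z)
  if (is.null(thin)) thin <- max(1L, n_iter %/% 20000L)
  logM <- vapply(orderings, function(o) subject_log_marginals(Z, es, o), numeric(n))
  logM <- matrix(logM, nrow = n)
  logf <- log(f)
  mix_loglik <- function(M) sum(row_logsumexp(sweep(M, 2L, logf, "+")))
  cur_ll <- mix_loglik(logM)
  best <- list(orderings = orderings, loglik = cur_ll)
  n_keep <- n_iter %/% thin
  samples <- lapply(seq_len(C), function(c) matrix(0L, n_keep, E))
  sample_ll <- numeric(n_keep)
  kept <- 0L
  accepted <- 0L
  pos_within <- order(orderings[[1L]]) # scratch, reassigned per proposal
  for (it in seq_len(n_iter)) {
    c <- if (C == 1L) 1L else sample.int(C, 1L)
    ij <- sample.int(E, 2L)
    prop <- orderings[[c]]
    prop[ij] <- prop[rev(ij)]
    if (valid_positions_fast(es, prop)) {
      new_col <- subject_log_marginals(Z, es, prop)
      M2 <- logM
      M2[, c] <- new_col
      new_ll <- mix_loglik(M2)
      if (new_ll >= cur_ll || log(stats::runif(1L)) < new_ll - cur_ll) {
        orderings[[c]] <- prop
        logM <- M2
        cur_ll <- new_ll
        accepted <- accepted + 1L
        if (cur_ll > best$loglik) best <- list(orderings = orderings, loglik = cur_ll)
      }
    }
    if (it %% thin == 0L) {
      kept <- kept + 1L
      for (cc in seq_len(C)) samples[[cc]][kept, ] <- orderings[[cc]]
      sample_ll[kept] <- cur_ll
    }
  }
  list(samples = samples, sample_loglik = sample_ll,
       acceptance_rate = accepted / n_iter, best = best, thin = thin)
}

## E x E positional density: rows = events (canonical index), cols = stage
## positions; entry = posterior frequency of event e at position p.
positional_density <- function(es, sample_matrix) {
  E <- es$E
  D <- matrix(0, E, E, dimnames = list(
    event = paste0(es$events$biomarker, "_z", es$events$level),
    position = seq_len(E)))
  n <- nrow(sample_matrix)
  for (p in seq_len(E)) {
    tab <- tabulate(sample_matrix[, p], nbins = E)
    D[, p] <- tab / n
  }
  D
}

new_subtype_model <- function(ordering, fraction, mcmc = NULL, es = NULL) {
  m <- list(ordering = ordering, fraction = fraction)
  if (!is.null(mcmc)) {
    m$mcmc_samples <- mcmc$samples
    m$positional_density <- positional_density(es, mcmc$samples)
  }
  class(m) <- "subtype_model"
  m
}

#' Fit the subtype mixture for a fixed number of subtypes
#'
#' Hierarchical fitting: the single-subtype model is fitted by multi-start
#' greedy ascent over constrained orderings; each larger model is
#' initialized by splitting one fitted cluster's subjects into random
#' halves, fitting each half, and jointly refining all orderings and
#' fractions by EM; the best split is kept. A Metropolis MCMC over
#' constrained pairwise swaps (at fixed fractions) then samples ordering
#' uncertainty and the positional densities.
#'
#' @param Z z-score matrix/data.frame (subjects x event-set biomarkers).
#' @param es an [event_set()].
#' @param C number of subtypes (1 <= C <= min(E, n)).
#' @param n_starts random starts for each greedy fit.
#' @param mcmc_iters Metropolis iterations (0 skips the MCMC stage).
#' @param seed RNG seed.
#' @param tol,max_iter EM convergence control (relative log-likelihood
#'   change; default 1e-6 / 100 iterations).
#' @param n_em_starts extra random-ordering EM initializations tried per
#'   added subtype, alongside the cluster splits.
#' @param em_explore_iter EM iteration cap while screening initializations
#'   (the winner is refined to full convergence).
#' @param max_passes greedy-ascent pass cap per start.
#' @return list of `C` subtype models (ordering, fraction, MCMC samples and
#'   positional density when `mcmc_iters > 0`), with attributes `loglik`,
#'   `loglik_trace` and `mcmc`.
#' @export
fit_fixed_C <- function(Z, es, C, n_starts = 10L, mcmc_iters = 10000L,
                        seed = NULL, tol = 1e-6, max_iter = 100L,
                        n_em_starts = 4L, em_explore_iter = 15L,
                        max_passes = 10L) {
  Z <- as_z_matrix(Z, es)
  n <- nrow(Z)
  if (C < 1L) stop_input("C must be >= 1")
  if (C > es$E || C > n) stop_input("C = %d exceeds E = %d or n = %d", C, es$E, n)
  maybe_seed(seed)

  fit1 <- fit_single(Z, es, n_starts = n_starts, max_passes = max_passes)
  orderings <- list(fit1$ordering)
  f <- 1
  loglik <- fit1$objective
  trace <- loglik
  R <- matrix(1, n, 1L)

  Cc <- 1L
  while (Cc < C) {
    hard <- max.col(R, ties.method = "first")
    ## candidate initializations: split each current cluster into random
    ## halves and fit each half; plus random-ordering restarts, which break
    ## the symmetry the split can leave when the halves are alike
    inits <- list()
    for (j in seq_len(Cc)) {
      idx <- which(hard == j)
      if (length(idx) < 4L) next
      halves <- split(sample(idx), rep(1:2, length.out = length(idx)))
      half_fit <- lapply(halves, function(h)
        fit_single(Z[h, , drop = FALSE], es, n_starts = max(2L, n_starts %/% 3L),
                   max_passes = min(5L, max_passes))$ordering)
      inits[[length(inits) + 1L]] <-
        list(orderings = c(orderings[-j], half_fit),
             f = c(f[-j], rep(f[j] / 2, 2)))
    }
    for (s in seq_len(n_em_starts)) {
      inits[[length(inits) + 1L]] <-
        list(orderings = lapply(seq_len(Cc + 1L), function(i) random_ordering(es)),
             f = rep(1 / (Cc + 1L), Cc + 1L))
    }
    if (!length(inits))
      stop_input("could not split any cluster to reach C = %d (clusters too small)", C)
    ## capped-exploration EM on every candidate, full refinement of the best
    best <- NULL
    for (ini in inits) {
      res <- em_refine(Z, es, ini$orderings, ini$f, tol = tol,
                       max_iter = em_explore_iter)
      if (is.null(best) || res$loglik > best$loglik) best <- res
    }
    best <- em_refine(Z, es, best$orderings, best$f, tol = tol,
                      max_iter = max_iter)
    orderings <- best$orderings
    f <- best$f
    loglik <- best$loglik
    trace <- best$loglik_trace
    R <- best$R
    Cc <- Cc + 1L
  }

  mcmc <- NULL
  if (mcmc_iters > 0L) {
    mcmc <- mcmc_orderings(Z, es, orderings, f, n_iter = mcmc_iters)
    if (mcmc$best$loglik > loglik + 1e-12) {
      ## MCMC found a better mode: adopt its orderings as the ML estimate
      orderings <- mcmc$best$orderings
      res <- em_refine(Z, es, orderings, f, tol = tol, max_iter = max_iter)
      orderings <- res$orderings
      f <- res$f
      loglik <- res$loglik
    }
  }

  models <- lapply(seq_len(C), function(c)
    new_subtype_model(orderings[[c]], f[c],
                      mcmc = if (is.null(mcmc)) NULL else list(samples = mcmc$samples[[c]]),
                      es = es))
  attr(models, "loglik") <- loglik
  attr(models, "loglik_trace") <- trace
  if (!is.null(mcmc)) attr(models, "mcmc") <- mcmc[c("acceptance_rate", "sample_loglik", "thin")]
  models
}

#' Ten-fold cross-validated information criterion over the number of subtypes
#'
#' Stratified random partition into `folds` test folds; for each fold the
#' model is fitted on the remaining data for every candidate `C` and the
#' held-out mixture log-likelihood is accumulated.
#' `CVIC(C) = -2 * sum(held-out log-likelihood)`, minimized by the
#' best-supported number of subtypes.
#'
#' @inheritParams fit_fixed_C
#' @param C_range integer vector of candidate subtype counts.
#' @param folds number of folds (default 10).
#' @param strata optional factor (e.g., disease group) for stratified folds.
#' @param n_starts,mcmc_iters passed to the per-fold fits; MCMC is skipped
#'   by default since held-out likelihood needs only the ML orderings.
#' @param ... further arguments passed to [fit_fixed_C()] (e.g.
#'   `n_em_starts`, `em_explore_iter`, `max_iter`) to trade fold-fit
#'   thoroughness for runtime.
#' @return list with `cvic` (named by C), `heldout_loglik`, `folds`
#'   (per-subject fold index) and `seed`.
#' @export
crossval_cvic <- function(Z, es, C_range = 1:2, folds = 10L, strata = NULL,
                          n_starts = 5L, mcmc_iters = 0L, seed = NULL, ...) {
  Z <- as_z_matrix(Z, es)
  n <- nrow(Z)
  if (folds > n) stop_input("more folds (%d) than subjects (%d)", folds, n)
  maybe_seed(seed)
  fold_id <- integer(n)
  strata <- if (is.null(strata)) factor(rep(1L, n)) else factor(strata)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  heldout <- matrix(0, folds, length(C_range),
                    dimnames = list(NULL, paste0("C", C_range)))
  for (fd in seq_len(folds)) {
    train <- Z[fold_id != fd, , drop = FALSE]
    test <- Z[fold_id == fd, , drop = FALSE]
    for (ci in seq_along(C_range)) {
      fit <- fit_fixed_C(train, es, C_range[ci], n_starts = n_starts,
                         mcmc_iters = mcmc_iters,
                         seed = derive_seed(seed %||% 0L, sprintf("cv%d_%d", fd, ci)), ...)
      heldout[fd, ci] <- loglik_dataset(test, es, fit)
    }
  }
  cvic <- -2 * colSums(heldout)
  names(cvic) <- paste0("C", C_range)
  list(cvic = cvic, C_range = C_range, heldout_loglik = heldout,
       folds = fold_id, seed = seed)
}

#' Select the number of subtypes from CVIC values
#'
#' Takes the CVIC minimizer, then repeatedly moves to the smallest simpler
#' model whose CVIC lies inside the similarity band of the current
#' candidate's (lower complexity is preferred when criteria are similar).
#' `parsimony_delta` is the full width of that band: two models count as
#' similar when their CVICs differ by at most `parsimony_delta / 2`. Ties
#' break toward smaller `C`.
#'
#' @param cvic numeric vector of CVIC values for C = 1, 2, ... (in order).
#' @param parsimony_delta similarity band width (default 6, i.e. CVIC
#'   differences up to 3 are treated as similar).
#' @return selected number of subtypes (integer).
#' @examples
#' select_C(c(100, 95, 94.5))  # 2
#' select_C(c(50, 60, 70))     # 1
#' @export
select_C <- function(cvic, parsimony_delta = 6) {
  if (length(cvic) < 1L || any(!is.finite(cvic))) stop_input("cvic must be finite and nonempty")
  cand <- which(cvic == min(cvic))[1L]
  repeat {
    smaller <- which(seq_along(cvic) < cand &
                       cvic <= cvic[cand] + parsimony_delta / 2)
    if (!length(smaller)) break
    cand <- min(smaller)
  }
  as.integer(cand)
}

#' Fit subtype-and-stage models across candidate subtype counts
#'
#' Runs [fit_fixed_C()] on the full data for each `C` in `1..C_max`,
#' computes the ten-fold [crossval_cvic()], and applies [select_C()].
#'
#' @inheritParams fit_fixed_C
#' @inheritParams crossval_cvic
#' @param C_max largest number of subtypes considered.
#' @param cv_n_starts random starts used inside cross-validation fits.
#' @param parsimony_delta passed to [select_C()].
#' @return an object of class `sustain_fit`: list with `event_set`, `models`
#'   (one list of subtype models per C), `loglik`, `cvic`, `selected_C`,
#'   `selected_models`, `cv` and `seed`.
#' @export
fit_sustain <- function(Z, es, C_max = 3L, folds = 10L, n_starts = 10L,
                        cv_n_starts = 5L, mcmc_iters = 10000L,
                        parsimony_delta = 6, strata = NULL, seed = NULL) {
  Z <- as_z_matrix(Z, es)
  models <- vector("list", C_max)
  loglik <- numeric(C_max)
  for (C in seq_len(C_max)) {
    models[[C]] <- fit_fixed_C(Z, es, C, n_starts = n_starts,
                               mcmc_iters = mcmc_iters,
                               seed = derive_seed(seed %||% 0L, paste0("fit", C)))
    loglik[C] <- attr(models[[C]], "loglik")
  }
  cv <- crossval_cvic(Z, es, C_range = seq_len(C_max), folds = folds,
                      strata = strata, n_starts = cv_n_starts,
                      n_em_starts = 2L, em_explore_iter = 8L, max_iter = 40L,
                      seed = derive_seed(seed %||% 0L, "cv"))
  selected <- select_C(cv$cvic, parsimony_delta)
  structure(
    list(event_set = es, models = models, loglik = loglik, cvic = cv$cvic,
         selected_C = selected, selected_models = models[[selected]],
         cv = cv, seed = seed),
    class = "sustain_fit"
  )
}

#' @export
print.sustain_fit <- function(x, ...) {
  cat(sprintf("Subtype-and-stage fit: %d biomarkers, E = %d events\n",
              length(x$event_set$biomarkers), x$event_set$E))
  cat("  CVIC:", paste(sprintf("C=%d: %.1f", seq_along(x$cvic), x$cvic),
                       collapse = ", "), "\n")
  cat(sprintf("  selected C = %d (fractions %s)\n", x$selected_C,
              paste(sprintf("%.2f", vapply(x$selected_models, `[[`, 1.0, "fraction")),
                    collapse = "/")))
  invisible(x)
}

#' Kendall rank agreement between two event orderings
#'
#' Kendall's tau between the stage positions two orderings assign to the
#' same events; 1 means identical order.
#'
#' @param o1,o2 ordering vectors of equal length.
#' @return Kendall's tau in `[-1, 1]`.
#' @export
ordering_kendall <- function(o1, o2) {
  stats::cor(order(o1), order(o2), method = "kendall")
}

#' Serialize a fitted model to JSON
#'
#' Writes the event set, per-C orderings and fractions, CVIC table, selected
#' C and seed in a human-diffable JSON layout; positional densities can be
#' exported separately with [utils::write.csv()].
#'
#' @param fit a `sustain_fit`.
#' @param path file path.
#' @return `path`, invisibly. `read_sustain_json()` restores the event set,
#'   orderings, fractions and selection (MCMC samples are not persisted).
#' @export
write_sustain_json <- function(fit, path) {
  obj <- list(
    event_set = list(biomarkers = fit$event_set$biomarkers,
                     z_levels = fit$event_set$z_levels,
                     z_max = as.list(fit$event_set$z_max),
                     sigma = as.list(fit$event_set$sigma)),
    models = lapply(fit$models, function(ms)
      lapply(ms, function(m) list(ordering = m$ordering, fraction = m$fraction))),
    loglik = fit$loglik,
    cvic = as.list(fit$cvic),
    selected_C = fit$selected_C,
    seed = fit$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sustain_json
#' @export
read_sustain_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  bm <- unlist(obj$event_set$biomarkers)
  es <- event_set(bm,
                  z_levels = lapply(obj$event_set$z_levels, unlist)[bm],
                  z_max = unlist(obj$event_set$z_max)[bm],
                  sigma = unlist(obj$event_set$sigma)[bm])
  models <- lapply(obj$models, function(ms)
    lapply(ms, function(m)
      new_subtype_model(as.integer(unlist(m$ordering)), as.numeric(m$fraction))))
  selected <- as.integer(obj$selected_C)
  structure(
    list(event_set = es, models = models, loglik = as.numeric(obj$loglik),
         cvic = unlist(obj$cvic), selected_C = selected,
         selected_models = models[[selected]], cv = NULL, seed = obj$seed),
    class = "sustain_fit"
  )
}
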