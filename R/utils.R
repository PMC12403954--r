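#' @keywords internal
"_PACKAGE"

## numerically stable log(sum(exp(x))) over a vector
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## row-wise logsumexp of a matrix
row_logsumexp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

## Log-marginals for column blocks of equal width.
## L: n x (S * ncand) matrix whose columns come in `ncand` contiguous blocks of
## width S; returns an n x ncand matrix of logsumexp over each block.
## Implemented with pmax/exp accumulation so no per-cell apply() is needed.
block_logsumexp <- function(L, S) {
  n <- nrow(L)
  ncand <- ncol(L) %/% S
  stopifnot(ncol(L) == S * ncand)
  ## columns of block c are (c-1)*S + (1:S)
  mx <- L[, seq.int(1L, by = S, length.out = ncand), drop = FALSE]
  if (S > 1L) {
    for (s in 2:S) {
      mx <- pmax(mx, L[, seq.int(s, by = S, length.out = ncand), drop = FALSE])
    }
  }
  acc <- matrix(0, n, ncand)
  for (s in 1:S) {
    acc <- acc + exp(L[, seq.int(s, by = S, length.out = ncand), drop = FALSE] - mx)
  }
  mx + log(acc)
}

## Deterministic per-stage seed derived from a master seed and a label,
## kept inside 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}

## set.seed only when a seed is supplied
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483647L)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
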