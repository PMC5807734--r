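# Internal numeric helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log-sum-exp
#' @param x numeric vector of log values.
#' @return log(sum(exp(x))) computed with a max shift.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix; rows with all -Inf stay -Inf.
row_logsumexp <- function(M) {
  m <- apply(M, 1L, max)
  out <- m + log(rowSums(exp(M - m)))
  bad <- !is.finite(m)
  if (any(bad)) out[bad] <- m[bad]
  out
}

# Evaluate an expression with a private RNG stream, restoring the caller's
# .Random.seed afterwards.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

DAY_YEARS <- 1 / 365.25
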