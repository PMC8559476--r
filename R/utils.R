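# internal numerical helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# symmetrise and invert an SPD matrix via Cholesky with a jitter fallback
sym_inv <- function(A) {
  A <- (A + t(A)) / 2
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- max(abs(diag(A)), 1e-12) * 1e-10
    ch <- chol(A + diag(jit, nrow(A)))
  }
  chol2inv(ch)
}

# log-determinant of an SPD matrix
sym_logdet <- function(A) {
  A <- (A + t(A)) / 2
  2 * sum(log(diag(chol(A))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
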