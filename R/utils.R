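# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

fc_stop <- function(...) stop(..., call. = FALSE)

fc_assert <- function(cond, ...) if (!isTRUE(cond)) fc_stop(...)

## round-half-up at `digits`, the convention used by the report tables
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_psd <- function(m, tol = 1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-8)) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(abs(ev), 1))
}

## draw n iid rows from N(0, Sigma); eigen-based so PSD matrices are accepted
rmvn_rows <- function(n, Sigma) {
  Sigma <- as.matrix(Sigma)
  t_ <- nrow(Sigma)
  if (t_ == 1L) return(matrix(stats::rnorm(n, sd = sqrt(Sigma[1, 1])), ncol = 1))
  e <- eigen(Sigma, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * t_), nrow = n)
  z %*% (e$vectors %*% diag(sqrt(ev), t_)) %*% t(e$vectors)
}
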