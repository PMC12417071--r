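`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# sub-seed derivation: keeps every RNG stream a pure function of one user seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 1000003 * as.numeric(k)) %% 2147483629)
}

softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

row_softmax <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

rand_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nrow = nr, ncol = nc)
}
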