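# Internal numerical utilities.

# Adam optimizer as a stateful closure; returns a function
# step(par, grad, lr = lr0) so callers can decay the rate across epochs.
make_adam <- function(n, lr = 0.005, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  lr0 <- lr
  m <- numeric(n)
  v <- numeric(n)
  t <- 0L
  function(par, grad, lr = lr0) {
    t <<- t + 1L
    m <<- beta1 * m + (1 - beta1) * grad
    v <<- beta2 * v + (1 - beta2) * grad^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    as.vector(par - lr * mhat / (sqrt(vhat) + eps))
  }
}

# Global-norm gradient clipping.
clip_grad <- function(g, max_norm) {
  g <- as.vector(g)
  nrm <- sqrt(sum(g^2))
  if (is.finite(nrm) && nrm > max_norm) g * (max_norm / nrm) else g
}

# Uniform init in +/- 1/sqrt(fan_in), the convention used for all GRU layers.
runif_fan <- function(n, fan_in) {
  a <- 1 / sqrt(fan_in)
  runif(n, -a, a)
}

one_hot <- function(i, n) {
  v <- numeric(n)
  if (!is.na(i)) {
    stopifnot(i >= 0, i < n)
    v[i + 1] <- 1
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_eidt <- function(...) stop(..., call. = FALSE)
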