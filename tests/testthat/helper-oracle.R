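# Independent reference implementation of the documented recurrence,
# written directly from the update-gate equations with plain R matrix ops.
# Used to cross-check the package's compiled forward passes.

ref_unpack <- function(theta, I, H, K = NULL) {
  off <- 0
  take <- function(nr, nc) {
    m <- matrix(theta[(off + 1):(off + nr * nc)], nr, nc)
    off <<- off + nr * nc
    m
  }
  w <- list(Wz = take(H, I), Wr = take(H, I), Wc = take(H, I),
            Uz = take(H, H), Ur = take(H, H), Uc = take(H, H),
            bz = drop(take(H, 1)), br = drop(take(H, 1)), bc = drop(take(H, 1)))
  if (!is.null(K)) w$Wout <- take(K, H)
  w
}

ref_sigmoid <- function(x) 1 / (1 + exp(-x))

# hidden states for an input matrix X (inputs x time), h_0 = 0
ref_gru_forward <- function(w, X) {
  H <- length(w$bz)
  L <- ncol(X)
  out <- matrix(0, H, L)
  h <- numeric(H)
  for (t in seq_len(L)) {
    x <- X[, t]
    u <- ref_sigmoid(w$Wz %*% x + w$Uz %*% h + w$bz)
    r <- ref_sigmoid(w$Wr %*% x + w$Ur %*% h + w$br)
    cd <- tanh(w$Wc %*% x + w$Uc %*% (r * h) + w$bc)
    h <- drop((1 - u) * h + u * cd)
    out[, t] <- h
  }
  out
}

# softmax-readout probabilities, time steps in rows
ref_solver_probs <- function(theta, I, Q, K, X) {
  w <- ref_unpack(theta, I, Q, K)
  H <- ref_gru_forward(w, X)
  V <- w$Wout %*% H
  t(apply(V, 2, function(v) { e <- exp(v - max(v)); e / sum(e) }))
}
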