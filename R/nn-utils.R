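# Minimal neural-network primitives with hand-written backpropagation.
# Parameters and gradients are flat named lists of numeric arrays; Adam
# state mirrors that structure.

relu <- function(x) (x > 0) * x

he_init <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

add_bias <- function(x, b) sweep(x, 2, b, "+")

# Blockwise log-softmax over a N x (G*B) score matrix whose columns are G
# consecutive blocks of width B (block index outer, within-block inner).
# `mask` is an optional length-(G*B) vector added to the scores (use -Inf to
# forbid an entry). Returns the N x (G*B) log-probability matrix.
block_log_softmax <- function(scores, B, mask = NULL) {
  N <- nrow(scores); GB <- ncol(scores); G <- GB %/% B
  if (!is.null(mask)) scores <- sweep(scores, 2, mask, "+")
  a <- aperm(array(scores, c(N, B, G)), c(1, 3, 2)) # (N, G, B)
  m2 <- matrix(a, N * G, B)
  mx <- do.call(pmax, lapply(seq_len(B), function(j) m2[, j]))
  lse <- mx + log(rowSums(exp(m2 - mx)))
  lp <- m2 - lse
  lp[is.nan(lp)] <- LOG_FLOOR # fully masked rows (cannot occur in practice)
  lp <- pmax(lp, LOG_FLOOR)
  matrix(aperm(array(lp, c(N, G, B)), c(1, 3, 2)), N, GB)
}

# Backward of block_log_softmax: g is the gradient w.r.t. the log-probs
# (same shape), logp the forward output; returns gradient w.r.t. scores.
# d score_i = g_i - p_i * sum_j g_j within each block; masked entries get 0.
block_log_softmax_bwd <- function(g, logp, B, mask = NULL) {
  N <- nrow(g); GB <- ncol(g); G <- GB %/% B
  ga <- matrix(aperm(array(g, c(N, B, G)), c(1, 3, 2)), N * G, B)
  pa <- exp(matrix(aperm(array(logp, c(N, B, G)), c(1, 3, 2)), N * G, B))
  ds <- ga - pa * rowSums(ga)
  ds <- matrix(aperm(array(ds, c(N, G, B)), c(1, 3, 2)), N, GB)
  if (!is.null(mask)) ds[, is.infinite(mask)] <- 0
  ds
}

adam_init <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam step (default hyperparameters: lr 1e-3, beta1 0.9, beta2 0.999).
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Accumulate two gradient lists with matching names.
grad_add <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}
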