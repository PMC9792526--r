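# Minimal vectorized neural-network primitives shared by the three
# architectures. Parameters live in named lists of matrices/vectors;
# gradients mirror that structure, so one Adam implementation serves all
# models.

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# mean cross-entropy of integer labels (0-based) against logit rows
ce_loss <- function(logits, labels) {
  p <- softmax_rows(logits)
  idx <- cbind(seq_along(labels), labels + 1L)
  -mean(log(pmax(p[idx], 1e-12)))
}

# mean binary cross-entropy of 0/1 labels against a logit column
bce_loss <- function(logits, labels) {
  p <- sigmoid(as.numeric(logits))
  -mean(labels * log(pmax(p, 1e-12)) +
          (1 - labels) * log(pmax(1 - p, 1e-12)))
}

# Glorot-style initialization for a dense layer
init_dense <- function(n_in, n_out) {
  s <- sqrt(2 / (n_in + n_out))
  list(W = matrix(rnorm(n_in * n_out, 0, s), n_in, n_out),
       b = numeric(n_out))
}

onehot <- function(labels, n_classes) {
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

# inverted dropout mask; scale kept units so eval needs no rescaling
dropout_mask <- function(n, m, rate) {
  if (rate <= 0) return(matrix(1, n, m))
  matrix(rbinom(n * m, 1, 1 - rate) / (1 - rate), n, m)
}

adam_state <- function(params) {
  zeros <- purrr::map(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

n_params <- function(params) {
  sum(purrr::map_int(params, length))
}
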