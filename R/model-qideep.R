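#' Quadratic-interaction (QI) layer
#'
#' The QI layer scores the pairwise interactions among the selected
#' features as a sum of latent-vector inner products weighted by the
#' feature-value products:
#' `y_QI = sum_{i<j} <V_i, V_j> x_i x_j`.
#' `qi_forward()` evaluates the full all-pairs sum through the
#' factorization-machine reformulation
#' `1/2 * sum_l [ (sum_i v_il x_i)^2 - sum_i v_il^2 x_i^2 ]`,
#' which costs O(n k) instead of O(n^2 k); `qi_forward_pairs()` evaluates
#' the restricted sum over an explicit pair list (the default inside a
#' QIDeep model, where only the screened order-2 pairs contribute).
#'
#' @param x Numeric vector of the QI-selected feature values (or a matrix
#'   with one row per sample).
#' @param V Latent matrix, one row (length `k`) per QI feature.
#' @param pairs Integer matrix with two columns of feature positions
#'   (1-based within `x`/`V` rows).
#' @return Numeric vector of QI outputs, one per sample.
#' @examples
#' V <- rbind(c(1, 0), c(0, 1), c(1, 1))
#' qi_forward(c(1, 2, 3), V)
#' @export
qi_forward <- function(x, V) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  V <- as.matrix(V)
  if (ncol(X) != nrow(V)) {
    stop("x has ", ncol(X), " features but V has ", nrow(V), " rows",
         call. = FALSE)
  }
  if (nrow(V) < 2) return(numeric(nrow(X)))
  S <- X %*% V                 # n x k, column l = sum_i v_il x_i
  Q <- (X^2) %*% (V^2)         # n x k, column l = sum_i v_il^2 x_i^2
  out <- 0.5 * rowSums(S^2 - Q)
  as.numeric(out)
}

#' @rdname qi_forward
#' @export
qi_forward_pairs <- function(x, V, pairs) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  V <- as.matrix(V)
  pairs <- as.matrix(pairs)
  out <- numeric(nrow(X))
  if (length(pairs) == 0) return(out)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    out <- out + sum(V[a, ] * V[b, ]) * X[, a] * X[, b]
  }
  out
}

#' QI-layer configuration
#'
#' @param pairs Two-column matrix (or list of length-2 vectors) of feature
#'   indices into the model input; each unordered pair appears once, no
#'   self-pairs.
#' @param latent_dim Length `k` of each latent vector (default 4).
#' @param all_pairs When TRUE the QI layer sums over every pair of the
#'   features occurring in `pairs` (full factorization-machine behaviour)
#'   instead of the listed pairs only.
#' @return A `qi_config` list with `pairs`, `latent_dim`,
#'   `qi_feature_indices` (the distinct features appearing in any pair)
#'   and `local_pairs` (pair positions re-indexed into that set).
#' @export
qi_config <- function(pairs, latent_dim = 4, all_pairs = FALSE) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) > 0) {
    if (any(pairs[, 1] == pairs[, 2])) {
      stop("self-pairs are not allowed", call. = FALSE)
    }
    pairs <- t(apply(pairs, 1, sort))
    pairs <- matrix(pairs, ncol = 2)
    key <- paste(pairs[, 1], pairs[, 2])
    if (anyDuplicated(key) > 0) stop("duplicate pairs", call. = FALSE)
  }
  stopifnot(latent_dim >= 1)
  feats <- sort(unique(as.integer(pairs)))
  local <- matrix(match(pairs, feats), ncol = 2)
  structure(
    list(pairs = pairs, latent_dim = as.integer(latent_dim),
         qi_feature_indices = feats, local_pairs = local,
         all_pairs = isTRUE(all_pairs)),
    class = "qi_config"
  )
}

#' Build a QIDeep model
#'
#' QIDeep augments the base network with a quadratic-interaction
#' component. The deep component (identical in shape to the base model:
#' hidden ReLU layer, dropout, 4 pre-activation outputs) sees all input
#' features; the QI component embeds the screened interaction features
#' into latent vectors and emits the scalar pairwise-interaction score.
#' The 5-vector concatenation `y_QI (+) y_DNN` feeds a trainable linear
#' output layer producing the 4 class logits; softmax is applied only when
#' probabilities are requested (training uses the logits directly in the
#' cross-entropy, avoiding vanishing gradients).
#'
#' An empty pair list is allowed and degenerates to the base network plus
#' a constant-zero extra input to the output layer.
#'
#' @param input_dim Number of input features.
#' @param qi A [qi_config()].
#' @param hidden_dim Deep-component hidden width (default 17).
#' @param dropout Dropout rate (default 0.2).
#' @param seed Seed for parameter initialization.
#' @return A `qideep_model` (also `strokeqi_model`).
#' @export
build_qideep <- function(input_dim, qi, hidden_dim = 17, dropout = 0.2,
                         seed = 1L) {
  stopifnot(inherits(qi, "qi_config"))
  if (length(qi$qi_feature_indices) > 0 &&
      max(qi$qi_feature_indices) > input_dim) {
    stop("QI feature index exceeds input_dim", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  l1 <- init_dense(input_dim, hidden_dim)
  l2 <- init_dense(hidden_dim, 4)
  m <- length(qi$qi_feature_indices)
  V <- matrix(rnorm(max(m, 1) * qi$latent_dim, 0, 0.1),
              max(m, 1), qi$latent_dim)
  if (m == 0) V <- V[0, , drop = FALSE]
  l3 <- init_dense(5, 4)
  structure(
    list(
      params = list(W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b,
                    V = V, W3 = l3$W, b3 = l3$b),
      qi = qi,
      config = list(input_dim = input_dim, hidden_dim = hidden_dim,
                    dropout = dropout, output_dim = 4L, seed = seed)
    ),
    class = c("qideep_model", "strokeqi_model")
  )
}

qideep_forward <- function(model, X, training = FALSE) {
  p <- model$params
  qi <- model$qi
  Z1 <- sweep(X %*% p$W1, 2, p$b1, "+")
  A1 <- relu(Z1)
  mask <- if (training) {
    dropout_mask(nrow(A1), ncol(A1), model$config$dropout)
  } else {
    NULL
  }
  D <- if (is.null(mask)) A1 else A1 * mask
  ydnn <- sweep(D %*% p$W2, 2, p$b2, "+")   # 4 pre-activation outputs
  Xq <- X[, qi$qi_feature_indices, drop = FALSE]
  yqi <- if (length(qi$qi_feature_indices) < 2) {
    numeric(nrow(X))
  } else if (qi$all_pairs) {
    qi_forward(Xq, p$V)
  } else {
    qi_forward_pairs(Xq, p$V, qi$local_pairs)
  }
  C <- cbind(yqi, ydnn)
  logits <- sweep(C %*% p$W3, 2, p$b3, "+")
  list(logits = logits, Z1 = Z1, D = D, mask = mask, X = X, Xq = Xq,
       C = C, yqi = yqi)
}

qideep_backward <- function(model, cache, dlogits) {
  p <- model$params
  qi <- model$qi
  dW3 <- crossprod(cache$C, dlogits)
  db3 <- colSums(dlogits)
  dC <- tcrossprod(dlogits, p$W3)
  dyqi <- dC[, 1]
  dydnn <- dC[, 2:5, drop = FALSE]

  dW2 <- crossprod(cache$D, dydnn)
  db2 <- colSums(dydnn)
  dD <- tcrossprod(dydnn, p$W2)
  dA1 <- if (is.null(cache$mask)) dD else dD * cache$mask
  dZ1 <- dA1 * (cache$Z1 > 0)
  dW1 <- crossprod(cache$X, dZ1)
  db1 <- colSums(dZ1)

  dV <- p$V * 0
  m <- length(qi$qi_feature_indices)
  if (m >= 2) {
    Xq <- cache$Xq
    if (qi$all_pairs) {
      # y = 1/2 sum_l [(Xq V)_l^2 - (Xq^2 V^2)_l]
      S <- Xq %*% p$V
      dV <- crossprod(Xq, dyqi * S) - p$V * as.numeric(crossprod(Xq^2, dyqi))
    } else if (nrow(qi$local_pairs) > 0) {
      for (r in seq_len(nrow(qi$local_pairs))) {
        a <- qi$local_pairs[r, 1]; b <- qi$local_pairs[r, 2]
        s <- sum(dyqi * Xq[, a] * Xq[, b])
        dV[a, ] <- dV[a, ] + s * p$V[b, ]
        dV[b, ] <- dV[b, ] + s * p$V[a, ]
      }
    }
  }
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, V = dV, W3 = dW3, b3 = db3)
}

#' @export
predict.qideep_model <- function(object, X, type = c("logits", "prob",
                                                     "class"), ...) {
  type <- match.arg(type)
  X <- as_input_matrix(X, object)
  logits <- qideep_forward(object, X, training = FALSE)$logits
  finish_prediction(logits, type, 4L)
}

qideep_loss_grad <- function(model, X, labels, training = TRUE) {
  cache <- qideep_forward(model, X, training = training)
  n <- nrow(X)
  P <- softmax_rows(cache$logits)
  loss <- ce_loss(cache$logits, labels)
  dlogits <- (P - onehot(labels, 4)) / n
  list(loss = loss, grads = qideep_backward(model, cache, dlogits))
}

#' @export
eval_loss.qideep_model <- function(model, X, labels) {
  ce_loss(qideep_forward(model, X, training = FALSE)$logits, labels)
}
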