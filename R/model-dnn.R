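#' Configure and build the base multilayer perceptron
#'
#' The four-state baseline is a fully connected network: input (one neuron
#' per feature) -> hidden layer of 17 ReLU units -> dropout at rate 0.2 ->
#' 4 output neurons. `output_dim = 1` gives the binary occurrence variant
#' (DNN-B), trained with a sigmoid + binary cross-entropy head.
#'
#' @param input_dim Number of input features.
#' @param hidden_dim Hidden-layer width (default 17).
#' @param dropout Dropout rate after the hidden layer, in `[0, 1)`.
#' @param output_dim 4 for the risk states, 1 for binary occurrence.
#' @param seed Seed for parameter initialization.
#' @return A `dnn_model` (also `strokeqi_model`) with randomly initialized
#'   parameters.
#' @examples
#' m <- build_base_dnn(34)
#' sum(lengths(m$params)) # 34*17 + 17 + 17*4 + 4 = 667
#' @export
build_base_dnn <- function(input_dim, hidden_dim = 17, dropout = 0.2,
                           output_dim = 4, seed = 1L) {
  stopifnot(input_dim >= 1, hidden_dim >= 1, dropout >= 0, dropout < 1,
            output_dim %in% c(1L, 4L))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  l1 <- init_dense(input_dim, hidden_dim)
  l2 <- init_dense(hidden_dim, output_dim)
  structure(
    list(
      params = list(W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b),
      config = list(input_dim = input_dim, hidden_dim = hidden_dim,
                    dropout = dropout, output_dim = output_dim,
                    seed = seed)
    ),
    class = c("dnn_model", "strokeqi_model")
  )
}

dnn_forward <- function(model, X, training = FALSE) {
  p <- model$params
  Z1 <- sweep(X %*% p$W1, 2, p$b1, "+")
  A1 <- relu(Z1)
  mask <- if (training) {
    dropout_mask(nrow(A1), ncol(A1), model$config$dropout)
  } else {
    NULL
  }
  D <- if (is.null(mask)) A1 else A1 * mask
  logits <- sweep(D %*% p$W2, 2, p$b2, "+")
  list(logits = logits, Z1 = Z1, D = D, mask = mask, X = X)
}

# dlogits: n x output_dim upstream gradient
dnn_backward <- function(model, cache, dlogits) {
  p <- model$params
  dW2 <- crossprod(cache$D, dlogits)
  db2 <- colSums(dlogits)
  dD <- tcrossprod(dlogits, p$W2)
  dA1 <- if (is.null(cache$mask)) dD else dD * cache$mask
  dZ1 <- dA1 * (cache$Z1 > 0)
  list(W1 = crossprod(cache$X, dZ1), b1 = colSums(dZ1),
       W2 = dW2, b2 = db2)
}

#' @export
predict.dnn_model <- function(object, X, type = c("logits", "prob",
                                                  "class"), ...) {
  type <- match.arg(type)
  X <- as_input_matrix(X, object)
  logits <- dnn_forward(object, X, training = FALSE)$logits
  finish_prediction(logits, type, object$config$output_dim)
}

as_input_matrix <- function(X, model) {
  if (inherits(X, "encoded_dataset")) X <- X$X
  X <- as.matrix(X)
  expected <- model$config$input_dim %||% ncol(X)
  if (ncol(X) != expected) {
    stop("input has ", ncol(X), " columns; model expects ", expected,
         call. = FALSE)
  }
  X
}

finish_prediction <- function(logits, type, output_dim) {
  if (type == "logits") return(logits)
  if (output_dim == 1) {
    p <- sigmoid(as.numeric(logits))
    if (type == "prob") return(p)
    return(as.integer(p > 0.5))
  }
  p <- softmax_rows(logits)
  if (type == "prob") return(p)
  as.integer(max.col(p) - 1L)
}

# loss + gradients for one minibatch; labels are 0-based classes or 0/1
dnn_loss_grad <- function(model, X, labels, training = TRUE) {
  cache <- dnn_forward(model, X, training = training)
  n <- nrow(X)
  if (model$config$output_dim == 1) {
    p <- sigmoid(as.numeric(cache$logits))
    loss <- bce_loss(cache$logits, labels)
    dlogits <- matrix((p - labels) / n, n, 1)
  } else {
    P <- softmax_rows(cache$logits)
    loss <- ce_loss(cache$logits, labels)
    dlogits <- (P - onehot(labels, 4)) / n
  }
  list(loss = loss, grads = dnn_backward(model, cache, dlogits))
}

eval_loss <- function(model, X, labels) {
  UseMethod("eval_loss")
}

#' @export
eval_loss.dnn_model <- function(model, X, labels) {
  logits <- dnn_forward(model, X, training = FALSE)$logits
  if (model$config$output_dim == 1) bce_loss(logits, labels)
  else ce_loss(logits, labels)
}
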