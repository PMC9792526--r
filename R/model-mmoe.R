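#' Build a two-objective multi-gate mixture-of-experts model
#'
#' Two experts extract shared representations from the encoded input:
#' Expert 1 is a single ReLU hidden layer of 11 units (the binary-DNN
#' style expert) and Expert 2 is a QIDeep body (hidden ReLU layer,
#' dropout, concatenated with the quadratic-interaction score, linearly
#' projected to the common width 11). Each objective owns a softmax gate,
#' a linear map of the input to nonnegative expert weights summing to 1;
#' the gated mixture `f^k(x) = sum_i g^k_i(x) f_i(x)` feeds that
#' objective's output head directly (no towers): a single logit + sigmoid
#' for stroke occurrence, four logits + softmax for the risk state. The
#' joint loss is the unweighted sum of the binary and multiclass
#' cross-entropies.
#'
#' @param input_dim Number of input features (typically the top-20
#'   selection).
#' @param qi A [qi_config()] for Expert 2's interaction component.
#' @param expert1_hidden Hidden width of Expert 1 (default 11, also the
#'   common mixing width).
#' @param expert2_hidden Hidden width of Expert 2's deep part (default 17).
#' @param dropout Dropout rate inside Expert 2 (default 0.2).
#' @param seed Seed for parameter initialization.
#' @return An `mmoe_model` (also `strokeqi_model`).
#' @export
build_mmoe <- function(input_dim, qi, expert1_hidden = 11,
                       expert2_hidden = 17, dropout = 0.2, seed = 1L) {
  stopifnot(inherits(qi, "qi_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  e1 <- init_dense(input_dim, expert1_hidden)
  e2h <- init_dense(input_dim, expert2_hidden)
  m <- length(qi$qi_feature_indices)
  V <- matrix(rnorm(max(m, 1) * qi$latent_dim, 0, 0.1),
              max(m, 1), qi$latent_dim)
  if (m == 0) V <- V[0, , drop = FALSE]
  proj <- init_dense(expert2_hidden + 1, expert1_hidden)
  g1 <- init_dense(input_dim, 2)
  g2 <- init_dense(input_dim, 2)
  occ <- init_dense(expert1_hidden, 1)
  risk <- init_dense(expert1_hidden, 4)
  structure(
    list(
      params = list(
        We1 = e1$W, be1 = e1$b,
        Wh = e2h$W, bh = e2h$b, V = V, Wp = proj$W, bp = proj$b,
        Wg1 = g1$W, bg1 = g1$b, Wg2 = g2$W, bg2 = g2$b,
        Wo = occ$W, bo = occ$b, Wr = risk$W, br = risk$b
      ),
      qi = qi,
      config = list(input_dim = input_dim, expert1_hidden = expert1_hidden,
                    expert2_hidden = expert2_hidden, dropout = dropout,
                    output_dim = 4L, seed = seed)
    ),
    class = c("mmoe_model", "strokeqi_model")
  )
}

mmoe_forward <- function(model, X, training = FALSE) {
  p <- model$params
  qi <- model$qi
  n <- nrow(X)
  # expert 1: single hidden layer
  Ze1 <- sweep(X %*% p$We1, 2, p$be1, "+")
  F1 <- relu(Ze1)
  # expert 2: QIDeep body -> common width
  Zh <- sweep(X %*% p$Wh, 2, p$bh, "+")
  Ah <- relu(Zh)
  mask <- if (training) {
    dropout_mask(n, ncol(Ah), model$config$dropout)
  } else {
    NULL
  }
  Dh <- if (is.null(mask)) Ah else Ah * mask
  Xq <- X[, qi$qi_feature_indices, drop = FALSE]
  yqi <- if (length(qi$qi_feature_indices) < 2) {
    numeric(n)
  } else if (qi$all_pairs) {
    qi_forward(Xq, p$V)
  } else {
    qi_forward_pairs(Xq, p$V, qi$local_pairs)
  }
  R2 <- cbind(Dh, yqi)
  F2 <- sweep(R2 %*% p$Wp, 2, p$bp, "+")
  # gates: one per objective, softmax over the two experts
  G1 <- softmax_rows(sweep(X %*% p$Wg1, 2, p$bg1, "+"))
  G2 <- softmax_rows(sweep(X %*% p$Wg2, 2, p$bg2, "+"))
  M1 <- G1[, 1] * F1 + G1[, 2] * F2   # occurrence mixture
  M2 <- G2[, 1] * F1 + G2[, 2] * F2   # risk mixture
  logits_occ <- sweep(M1 %*% p$Wo, 2, p$bo, "+")
  logits_risk <- sweep(M2 %*% p$Wr, 2, p$br, "+")
  list(logits_occ = logits_occ, logits_risk = logits_risk,
       X = X, Xq = Xq, Ze1 = Ze1, F1 = F1, Zh = Zh, Dh = Dh, mask = mask,
       yqi = yqi, R2 = R2, F2 = F2, G1 = G1, G2 = G2, M1 = M1, M2 = M2)
}

mmoe_backward <- function(model, cache, dlo, dlr) {
  p <- model$params
  qi <- model$qi
  g <- purrr::map(p, function(x) x * 0)

  g$Wo <- crossprod(cache$M1, dlo); g$bo <- colSums(dlo)
  g$Wr <- crossprod(cache$M2, dlr); g$br <- colSums(dlr)
  dM1 <- tcrossprod(dlo, p$Wo)
  dM2 <- tcrossprod(dlr, p$Wr)

  dF1 <- cache$G1[, 1] * dM1 + cache$G2[, 1] * dM2
  dF2 <- cache$G1[, 2] * dM1 + cache$G2[, 2] * dM2

  # gate gradients through the softmax
  for (k in 1:2) {
    dM <- if (k == 1) dM1 else dM2
    G <- if (k == 1) cache$G1 else cache$G2
    dg <- cbind(rowSums(dM * cache$F1), rowSums(dM * cache$F2))
    dglogits <- G * (dg - rowSums(G * dg))
    if (k == 1) {
      g$Wg1 <- crossprod(cache$X, dglogits); g$bg1 <- colSums(dglogits)
    } else {
      g$Wg2 <- crossprod(cache$X, dglogits); g$bg2 <- colSums(dglogits)
    }
  }

  # expert 1
  dZe1 <- dF1 * (cache$Ze1 > 0)
  g$We1 <- crossprod(cache$X, dZe1); g$be1 <- colSums(dZe1)

  # expert 2 projection
  g$Wp <- crossprod(cache$R2, dF2); g$bp <- colSums(dF2)
  dR2 <- tcrossprod(dF2, p$Wp)
  h <- model$config$expert2_hidden
  dDh <- dR2[, seq_len(h), drop = FALSE]
  dyqi <- dR2[, h + 1]
  dAh <- if (is.null(cache$mask)) dDh else dDh * cache$mask
  dZh <- dAh * (cache$Zh > 0)
  g$Wh <- crossprod(cache$X, dZh); g$bh <- colSums(dZh)

  m <- length(qi$qi_feature_indices)
  if (m >= 2) {
    Xq <- cache$Xq
    if (qi$all_pairs) {
      S <- Xq %*% p$V
      g$V <- crossprod(Xq, dyqi * S) -
        p$V * as.numeric(crossprod(Xq^2, dyqi))
    } else if (nrow(qi$local_pairs) > 0) {
      for (r in seq_len(nrow(qi$local_pairs))) {
        a <- qi$local_pairs[r, 1]; b <- qi$local_pairs[r, 2]
        s <- sum(dyqi * Xq[, a] * Xq[, b])
        g$V[a, ] <- g$V[a, ] + s * p$V[b, ]
        g$V[b, ] <- g$V[b, ] + s * p$V[a, ]
      }
    }
  }
  g
}

#' Joint two-objective loss
#'
#' Total loss of a label batch under the two heads: the sum over samples
#' of the binary cross-entropy of the occurrence head plus the sum of the
#' multiclass cross-entropy of the risk head (unweighted). Training
#' minimizes this quantity divided by the batch size.
#'
#' @param logits_occ Occurrence logits (length n or n x 1).
#' @param logits_risk n x 4 risk logits.
#' @param y Occurrence labels (0/1).
#' @param z Risk labels (0-3).
#' @return A single number, the summed joint loss.
#' @export
mmoe_loss <- function(logits_occ, logits_risk, y, z) {
  stopifnot(length(y) == length(z),
            NROW(logits_occ) == length(y), nrow(logits_risk) == length(z))
  if (any(!y %in% 0:1) || any(!z %in% 0:3)) {
    stop("labels out of range", call. = FALSE)
  }
  n <- length(y)
  n * bce_loss(logits_occ, y) + n * ce_loss(logits_risk, z)
}

# labels for mmoe training travel as a list(y = occurrence, z = risk)
mmoe_loss_grad <- function(model, X, labels, training = TRUE) {
  cache <- mmoe_forward(model, X, training = training)
  n <- nrow(X)
  y <- labels$y; z <- labels$z
  po <- sigmoid(as.numeric(cache$logits_occ))
  Pr <- softmax_rows(cache$logits_risk)
  loss <- bce_loss(cache$logits_occ, y) + ce_loss(cache$logits_risk, z)
  dlo <- matrix((po - y) / n, n, 1)
  dlr <- (Pr - onehot(z, 4)) / n
  list(loss = loss, grads = mmoe_backward(model, cache, dlo, dlr))
}

#' @export
eval_loss.mmoe_model <- function(model, X, labels) {
  cache <- mmoe_forward(model, X, training = FALSE)
  bce_loss(cache$logits_occ, labels$y) +
    ce_loss(cache$logits_risk, labels$z)
}

#' Predictions from a fitted MMOE model
#'
#' @param object An `mmoe_model`.
#' @param X Encoded matrix or `encoded_dataset`.
#' @param type `"logits"` (list of both heads), `"prob"`, or `"class"`.
#' @param ... Unused.
#' @return For `"logits"`/`"prob"` a list with `occurrence` and `risk`;
#'   for `"class"` a list with the 0/1 occurrence call and 0-3 risk call.
#' @export
predict.mmoe_model <- function(object, X, type = c("logits", "prob",
                                                   "class"), ...) {
  type <- match.arg(type)
  X <- as_input_matrix(X, object)
  cache <- mmoe_forward(object, X, training = FALSE)
  if (type == "logits") {
    return(list(occurrence = as.numeric(cache$logits_occ),
                risk = cache$logits_risk))
  }
  po <- sigmoid(as.numeric(cache$logits_occ))
  pr <- softmax_rows(cache$logits_risk)
  if (type == "prob") return(list(occurrence = po, risk = pr))
  list(occurrence = as.integer(po > 0.5),
       risk = as.integer(max.col(pr) - 1L))
}

#' Per-sample gate weights of a fitted MMOE model
#'
#' @param model An `mmoe_model`.
#' @param X Encoded matrix or `encoded_dataset`.
#' @return Tibble with one row per sample and objective: `objective`
#'   ("occurrence"/"risk"), `expert1`, `expert2`.
#' @export
gate_weights <- function(model, X) {
  stopifnot(inherits(model, "mmoe_model"))
  X <- as_input_matrix(X, model)
  cache <- mmoe_forward(model, X, training = FALSE)
  dplyr::bind_rows(
    tibble::tibble(objective = "occurrence", sample = seq_len(nrow(X)),
                   expert1 = cache$G1[, 1], expert2 = cache$G1[, 2]),
    tibble::tibble(objective = "risk", sample = seq_len(nrow(X)),
                   expert1 = cache$G2[, 1], expert2 = cache$G2[, 2])
  )
}
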