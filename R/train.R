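#' Training configuration
#'
#' Defaults follow the study setup: Adam with learning rate 0.01 and an
#' early-stop patience of 20 non-improving validation epochs. The batch
#' size (not reported in the study) defaults to 256.
#'
#' @param learning_rate Adam step size (default 0.01).
#' @param patience Consecutive non-improving validation epochs tolerated
#'   before stopping (default 20).
#' @param max_epochs Hard epoch cap (default 200).
#' @param batch_size Minibatch size (default 256).
#' @param val_fraction Fraction of the training data held out (stratified
#'   by the risk label) for early-stopping validation (default 0.1).
#' @param monitor Validation quantity watched by early stopping:
#'   `"total"` (the model's full loss) or `"primary"` (the risk-state
#'   cross-entropy only). For single-objective models the two coincide;
#'   for the two-objective model `"primary"` stops on the main risk
#'   objective, so the quickly-converging binary auxiliary task cannot
#'   cut training short. Default `"primary"`.
#' @param seed Seed controlling shuffling, dropout, and the validation
#'   carve-out.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, patience = 20,
                         max_epochs = 200, batch_size = 256,
                         val_fraction = 0.1,
                         monitor = c("primary", "total"), seed = 1L) {
  stopifnot(learning_rate > 0, patience >= 0, max_epochs >= 1,
            batch_size >= 1, val_fraction > 0, val_fraction < 1)
  monitor <- match.arg(monitor)
  structure(
    list(learning_rate = learning_rate, patience = as.integer(patience),
         max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size),
         val_fraction = val_fraction, monitor = monitor,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

# validation quantity watched by early stopping; equals eval_loss()
# except for the two-objective model under monitor = "primary", where
# only the risk-state cross-entropy is watched
eval_monitor <- function(model, X, labels, monitor) {
  if (identical(monitor, "primary") && inherits(model, "mmoe_model")) {
    cache <- mmoe_forward(model, X, training = FALSE)
    return(ce_loss(cache$logits_risk, labels$z))
  }
  eval_loss(model, X, labels)
}

model_loss_grad <- function(model, X, labels, training) {
  if (inherits(model, "mmoe_model")) {
    mmoe_loss_grad(model, X, labels, training)
  } else if (inherits(model, "qideep_model")) {
    qideep_loss_grad(model, X, labels, training)
  } else {
    dnn_loss_grad(model, X, labels, training)
  }
}

subset_labels <- function(labels, idx) {
  if (is.list(labels)) purrr::map(labels, ~ .x[idx]) else labels[idx]
}

strat_var <- function(labels) {
  if (is.list(labels)) labels$z else labels
}

#' Train a model with Adam and early stopping
#'
#' Minimizes the model's loss (multiclass cross-entropy for the base DNN
#' and QIDeep, binary cross-entropy for the binary DNN, the joint
#' two-objective loss for MMOE) by minibatch Adam. A stratified
#' `val_fraction` of the training rows is held out; training stops once
#' the validation loss has failed to improve for `config$patience`
#' consecutive epochs, and the parameters of the best validation epoch
#' are restored. Fully deterministic for a fixed `config$seed`.
#'
#' @param model A `strokeqi_model` from [build_base_dnn()],
#'   [build_qideep()] or [build_mmoe()].
#' @param X Training matrix or `encoded_dataset`.
#' @param labels For DNN/QIDeep: integer labels (risk 0-3, or 0/1 for a
#'   binary DNN). For MMOE: a list `list(y = occurrence, z = risk)`.
#'   When `X` is an `encoded_dataset` and `labels` is NULL the labels are
#'   taken from it.
#' @param config A [train_config()].
#' @return The fitted model, with `history` (tibble of epoch losses),
#'   `best_epoch`, `stopped_epoch` and `config` attached.
#' @export
train <- function(model, X, labels = NULL, config = train_config()) {
  stopifnot(inherits(model, "strokeqi_model"),
            inherits(config, "train_config"))
  if (inherits(X, "encoded_dataset")) {
    if (is.null(labels)) {
      labels <- if (inherits(model, "mmoe_model")) {
        list(y = X$occurrence, z = X$risk)
      } else if (model$config$output_dim == 1) {
        X$occurrence
      } else {
        X$risk
      }
    }
    X <- X$X
  }
  X <- as.matrix(X)
  n <- nrow(X)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  # stratified validation carve-out
  sv <- strat_var(labels)
  val_idx <- unlist(lapply(unique(sv), function(cls) {
    idx <- which(sv == cls)
    k <- max(1L, round(length(idx) * config$val_fraction))
    if (length(idx) <= 1) return(integer(0))
    sample(idx, min(k, length(idx) - 1L))
  }))
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- subset_labels(labels, tr_idx)
  Xva <- X[val_idx, , drop = FALSE]; yva <- subset_labels(labels, val_idx)

  state <- adam_state(model$params)
  best <- list(params = model$params, val = Inf, epoch = 0L)
  wait <- 0L
  hist <- vector("list", config$max_epochs)
  ntr <- nrow(Xtr)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(ntr)
    starts <- seq(1, ntr, by = config$batch_size)
    tl <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1, ntr)]
      lg <- model_loss_grad(model, Xtr[idx, , drop = FALSE],
                            subset_labels(ytr, idx), training = TRUE)
      if (!is.finite(lg$loss)) {
        stop("non-finite training loss at epoch ", epoch, call. = FALSE)
      }
      upd <- adam_step(model$params, lg$grads, state, config$learning_rate)
      model$params <- upd$params
      state <- upd$state
      tl <- tl + lg$loss * length(idx)
    }
    val <- eval_monitor(model, Xva, yva, config$monitor %||% "primary")
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = tl / ntr, val_loss = val
    )
    if (val < best$val - 1e-9) {
      best <- list(params = model$params, val = val, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config$patience) break
    }
  }

  model$params <- best$params
  model$history <- dplyr::bind_rows(hist)
  model$best_epoch <- best$epoch
  model$best_val_loss <- best$val
  model$stopped_epoch <- max(model$history$epoch)
  model$train_config <- config
  model$fitted <- TRUE
  model
}

#' @export
print.strokeqi_model <- function(x, ...) {
  kind <- class(x)[1]
  cat("<", kind, "> ", n_params(x$params), " parameters", sep = "")
  if (isTRUE(x$fitted)) {
    cat("; trained ", x$stopped_epoch, " epochs (best epoch ",
        x$best_epoch, ", val loss ", signif(x$best_val_loss, 4), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Broom-style tidiers for fitted models
#'
#' `tidy()` returns the per-epoch training history; `glance()` returns a
#' one-row model summary (parameter count, epochs run, best epoch and its
#' validation loss).
#'
#' @param x A fitted `strokeqi_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.strokeqi_model <- function(x, ...) {
  if (is.null(x$history)) {
    stop("model has not been trained", call. = FALSE)
  }
  x$history
}

#' @rdname tidy.strokeqi_model
#' @export
glance.strokeqi_model <- function(x, ...) {
  tibble::tibble(
    model = class(x)[1],
    n_parameters = n_params(x$params),
    epochs = x$stopped_epoch %||% NA_integer_,
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_loss = x$best_val_loss %||% NA_real_
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Save / load a fitted model as JSON
#'
#' Parameters and configuration are stored as plain JSON so checkpoints
#' are text files.
#'
#' @param model A `strokeqi_model`.
#' @param path File path.
#' @return `load_model()` returns the model; `save_model()` the path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  payload <- list(
    class = class(model),
    params = purrr::map(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    }),
    config = model$config,
    qi = if (!is.null(model$qi)) {
      list(pairs = as.integer(model$qi$pairs),
           n_pairs = nrow(model$qi$pairs),
           latent_dim = model$qi$latent_dim,
           all_pairs = model$qi$all_pairs)
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- purrr::map(payload$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2) {
      matrix(p$data, p$dim[1], p$dim[2])
    } else {
      as.numeric(p$data)
    }
  })
  model <- list(params = params, config = as.list(payload$config))
  if (!is.null(payload$qi$n_pairs)) {
    pairs <- matrix(as.integer(payload$qi$pairs),
                    nrow = payload$qi$n_pairs)
    model$qi <- qi_config(pairs, payload$qi$latent_dim,
                          payload$qi$all_pairs)
  }
  class(model) <- payload$class
  model
}
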