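test_that("QI reformulation matches the brute-force pairwise sum", {
  V <- rbind(c(1, 0), c(0, 1), c(1, 1))
  x <- c(1, 2, 3)
  expect_equal(qi_forward(x, V), qi_brute(x, V))

  expect_equal(qi_forward(c(2, 3), matrix(0, 2, 4)), 0)
  expect_equal(qi_forward(5, matrix(1, 1, 3)), 0)      # no pairs

  set.seed(42)
  for (case in 1:50) {
    n <- sample(2:10, 1)
    k <- sample(1:6, 1)
    V <- matrix(rnorm(n * k), n, k)
    x <- rnorm(n)
    expect_equal(qi_forward(x, V), qi_brute(x, V), tolerance = 1e-10)
  }
})

test_that("restricted pair sum agrees with per-pair arithmetic", {
  set.seed(7)
  V <- matrix(rnorm(5 * 3), 5, 3)
  x <- rnorm(5)
  pairs <- rbind(c(1, 3), c(2, 5))
  manual <- sum(V[1, ] * V[3, ]) * x[1] * x[3] +
    sum(V[2, ] * V[5, ]) * x[2] * x[5]
  expect_equal(qi_forward_pairs(x, V, pairs), manual)
  # all pairs listed == full sum
  allp <- t(combn(5, 2))
  expect_equal(qi_forward_pairs(x, V, allp), qi_forward(x, V),
               tolerance = 1e-10)
})

test_that("qi_config rejects malformed pair lists", {
  expect_error(qi_config(rbind(c(1, 1))), "self-pairs")
  expect_error(qi_config(rbind(c(1, 2), c(2, 1))), "duplicate")
  cfg <- qi_config(rbind(c(4, 2), c(1, 3)))
  expect_equal(cfg$qi_feature_indices, 1:4)
  expect_equal(nrow(cfg$local_pairs), 2)
})

test_that("base DNN has the documented parameter count and softmax head", {
  m <- build_base_dnn(34)
  expect_equal(sum(lengths(m$params)), 34 * 17 + 17 + 17 * 4 + 4) # 667
  X <- matrix(rnorm(5 * 34), 5, 34)
  p <- predict(m, X, type = "prob")
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # dropout disabled at inference: repeated forward passes identical
  expect_identical(predict(m, X), predict(m, X))
})

test_that("QIDeep embeds one latent vector per distinct QI feature", {
  # 3 pairs among 7 features, k = 4 -> 28 embedding entries
  pairs <- rbind(c(1, 2), c(3, 4), c(5, 7))
  qi <- qi_config(pairs, latent_dim = 4)
  m <- build_qideep(7, qi)
  expect_equal(dim(m$params$V), c(6, 4))
  qi2 <- qi_config(rbind(c(1, 2), c(2, 3), c(1, 3)), latent_dim = 4)
  m2 <- build_qideep(7, qi2)
  expect_equal(length(m2$params$V), 3 * 4)

  # logits are exposed un-normalized; probabilities normalize
  X <- matrix(rnorm(4 * 7), 4, 7)
  lg <- predict(m, X, type = "logits")
  expect_false(isTRUE(all.equal(rowSums(lg), rep(1, 4))))
  expect_equal(rowSums(predict(m, X, type = "prob")), rep(1, 4),
               tolerance = 1e-6)
})

test_that("QIDeep with no pairs degenerates to the deep component alone", {
  qi <- qi_config(matrix(integer(0), 0, 2))
  m <- build_qideep(6, qi, seed = 3)
  X <- matrix(rnorm(8 * 6), 8, 6)
  # manual composition: zero QI input concatenated with deep outputs
  p <- m$params
  A1 <- pmax(sweep(X %*% p$W1, 2, p$b1, "+"), 0)
  ydnn <- sweep(A1 %*% p$W2, 2, p$b2, "+")
  manual <- sweep(cbind(0, ydnn) %*% p$W3, 2, p$b3, "+")
  expect_equal(predict(m, X, type = "logits"), manual,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("MMOE gates are a convex combination over exactly two experts", {
  qi <- qi_config(rbind(c(1, 2)))
  m <- build_mmoe(6, qi, seed = 5)
  X <- matrix(rnorm(20 * 6), 20, 6)
  gw <- gate_weights(m, X)
  expect_equal(nrow(gw), 40)  # 2 objectives x 20 samples
  expect_equal(gw$expert1 + gw$expert2, rep(1, 40), tolerance = 1e-6)
  expect_true(all(gw$expert1 >= 0 & gw$expert2 >= 0))

  # forcing a gate to one expert reproduces that expert's head output:
  # perturbing the other expert must not change predictions
  m1 <- m
  m1$params$bg1 <- c(50, -50)   # occurrence gate -> expert 1
  m1$params$bg2 <- c(50, -50)   # risk gate -> expert 1
  m2 <- m1
  m2$params$Wh <- m2$params$Wh + 1   # perturb expert 2 only
  m2$params$V <- m2$params$V + 1
  p1 <- predict(m1, X)
  p2 <- predict(m2, X)
  expect_equal(p1$occurrence, p2$occurrence, tolerance = 1e-10)
  expect_equal(p1$risk, p2$risk, tolerance = 1e-10)
})

test_that("joint loss is the sum of binary and multiclass cross-entropies", {
  # hand-set logits: BCE at logit 0, true 1 is ln 2 per sample
  lo <- c(0, 0)
  lr <- rbind(rep(0, 4), c(1, 0, 0, 0))
  manual_bce <- 2 * log(2)
  manual_ce <- -log(0.25) - log(exp(1) / (exp(1) + 3))
  expect_equal(mmoe_loss(lo, lr, y = c(1, 1), z = c(0, 0)),
               manual_bce + manual_ce, tolerance = 1e-12)

  # confident perfect predictions drive the loss toward zero
  big <- 50
  loss <- mmoe_loss(c(big, -big),
                    rbind(c(big, 0, 0, 0), c(0, 0, big, 0)),
                    y = c(1, 0), z = c(0, 2))
  expect_lt(loss, 1e-8)

  expect_error(mmoe_loss(c(0), rbind(rep(0, 4)), y = 2, z = 0),
               "out of range")
  expect_error(mmoe_loss(c(0), rbind(rep(0, 4)), y = 1, z = 5),
               "out of range")
})

test_that("training is deterministic, restores the best epoch, and honors patience", {
  set.seed(31)
  n <- 400
  X <- matrix(runif(n * 2, -1, 1), n, 2)
  y <- (X[, 1] > 0) * 2L + (X[, 2] > 0) * 1L

  m1 <- train(build_base_dnn(2, seed = 7), X, y,
              quick_config(seed = 7, max_epochs = 60))
  m2 <- train(build_base_dnn(2, seed = 7), X, y,
              quick_config(seed = 7, max_epochs = 60))
  expect_identical(m1$params, m2$params)

  h <- tidy(m1)
  expect_equal(m1$best_val_loss, min(h$val_loss))
  expect_equal(m1$best_epoch, which.min(h$val_loss))

  # patience 0: stops at the first non-improving epoch
  m0 <- train(build_base_dnn(2, seed = 7), X, y,
              train_config(max_epochs = 100, patience = 0,
                           batch_size = 128, seed = 7))
  h0 <- tidy(m0)
  worse <- which(h0$val_loss >= dplyr::lag(h0$val_loss,
                                           default = Inf) - 1e-9)
  expect_equal(m0$stopped_epoch, min(worse))
})

test_that("the base network separates a quadrant toy problem", {
  set.seed(13)
  n <- 800
  X <- matrix(runif(n * 2, -1, 1), n, 2)
  y <- (X[, 1] > 0) * 2L + (X[, 2] > 0) * 1L
  m <- train(build_base_dnn(2, seed = 13), X, y,
             train_config(max_epochs = 200, batch_size = 64, seed = 13))
  expect_gt(mean(predict(m, X, type = "class") == y), 0.95)
})

test_that("fitted models round-trip through JSON checkpoints", {
  qi <- qi_config(rbind(c(1, 2), c(3, 4)))
  X <- matrix(rnorm(30 * 6), 30, 6)
  for (m in list(build_base_dnn(6, seed = 2),
                 build_qideep(6, qi, seed = 2),
                 build_mmoe(6, qi, seed = 2))) {
    path <- withr::local_tempfile(fileext = ".json")
    save_model(m, path)
    back <- load_model(path)
    expect_equal(class(back), class(m))
    if (inherits(m, "mmoe_model")) {
      expect_equal(predict(back, X)$risk, predict(m, X)$risk,
                   tolerance = 1e-12)
    } else {
      expect_equal(predict(back, X), predict(m, X), tolerance = 1e-12)
    }
  }
})

test_that("tidy and glance summarize a fitted model", {
  tab <- clean_table(small_table(n = 200, seed = 15), quiet = TRUE)
  ds <- encode(tab)
  m <- train(build_base_dnn(34, seed = 1), ds,
             config = quick_config(seed = 1, max_epochs = 10))
  h <- tidy(m)
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(h)))
  g <- glance(m)
  expect_equal(g$model, "dnn_model")
  expect_equal(g$n_parameters, 667)
  expect_error(tidy(build_base_dnn(34)), "not been trained")
})
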