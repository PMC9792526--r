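test_that("exact Shapley satisfies efficiency, symmetry, and dummy", {
  set.seed(21)
  bg <- matrix(rnorm(8 * 4), 8, 4)
  bg[, 2] <- bg[, 1]   # interchangeable players need a symmetric value fn

  # symmetric in features 1 and 2; feature 4 is ignored (dummy)
  f <- function(X) matrix(X[, 1] + X[, 2] + 3 * X[, 1] * X[, 2] +
                            X[, 3]^2, ncol = 1)
  x <- c(1.5, 1.5, -0.7, 2.2)
  phi <- exact_shapley(f, x, bg)

  # efficiency: exact additive decomposition
  expect_equal(sum(phi),
               as.numeric(attr(phi, "model_output") - attr(phi, "y_base")),
               tolerance = 1e-10)
  # symmetry: interchangeable features with equal values get equal credit
  expect_equal(as.numeric(phi[1, ]), as.numeric(phi[2, ]),
               tolerance = 1e-10)
  # dummy: the ignored feature gets exactly zero
  expect_equal(as.numeric(phi[4, ]), 0, tolerance = 1e-12)
})

test_that("exact Shapley reproduces closed forms", {
  # linear model, single background row: phi_j = w_j (x_j - b_j)
  w <- c(2, -1, 0.5)
  f <- function(X) matrix(X %*% w, ncol = 1)
  x <- c(1, 2, 3)
  b <- matrix(c(0.5, -1, 2), 1, 3)
  phi <- exact_shapley(f, x, b)
  expect_equal(as.numeric(phi), w * (x - as.numeric(b)),
               tolerance = 1e-10)

  # hand-enumerated interaction case
  f2 <- function(X) matrix(X[, 1] * X[, 2] + X[, 3], ncol = 1)
  phi2 <- exact_shapley(f2, c(1, 1, 1), matrix(0, 1, 3))
  expect_equal(as.numeric(phi2), c(0.5, 0.5, 1.0), tolerance = 1e-12)

  expect_error(exact_shapley(f, rnorm(13), matrix(0, 1, 13)),
               "limited to 12")
})

test_that("exact Shapley works per class on multi-output models", {
  f <- function(X) cbind(X[, 1], -X[, 1] + 2 * X[, 2])
  bg <- matrix(rnorm(12), 6, 2)
  x <- c(1, -1)
  phi <- exact_shapley(f, x, bg)
  expect_equal(dim(phi), c(2, 2))
  out <- attr(phi, "model_output")
  expect_equal(colSums(phi), out - attr(phi, "y_base"),
               tolerance = 1e-10)
})

test_that("permutation sampling converges to the exact value and is seeded", {
  f <- function(X) matrix(2 * X[, 1] + X[, 2] * X[, 3] -
                            0.5 * X[, 4]^2 + 0 * X[, 5], ncol = 1)
  set.seed(1)
  bg <- matrix(rnorm(10 * 5), 10, 5)
  x <- c(1, 0.5, -1, 2, 0.3)
  ex <- exact_shapley(f, x, bg)

  s1 <- sampled_shapley(f, x, bg, n_permutations = 400, seed = 5)
  s2 <- sampled_shapley(f, x, bg, n_permutations = 400, seed = 5)
  expect_identical(s1, s2)

  # efficiency enforced to numerical precision
  expect_equal(sum(s1),
               as.numeric(attr(s1, "model_output") - attr(s1, "y_base")),
               tolerance = 1e-9)

  # estimator error shrinks with the permutation budget
  err <- sapply(c(10, 100, 600), function(np) {
    mean(sapply(1:10, function(s) {
      mean(abs(sampled_shapley(f, x, bg, np, seed = s) - ex))
    }))
  })
  expect_true(all(diff(err) < 0))
})

test_that("importance ranks by mean |phi| with stable ties", {
  phi <- array(0, c(1, 2, 4),
               dimnames = list(NULL, c("A", "B"),
                               c("low", "medium", "high", "attack")))
  phi[1, , 3] <- c(-2, 1)
  attrs <- structure(
    list(phi = phi, y_base = rep(0, 4), model_output = matrix(0, 1, 4),
         feature_names = c("A", "B"),
         classes = c("low", "medium", "high", "attack"),
         rows = 1L, X = matrix(0, 1, 2)),
    class = "attribution_set"
  )
  imp <- importance(attrs)
  expect_equal(imp$high, c(2, 1))
  expect_equal(imp$overall, c(0.5, 0.25))

  # all-zero attributions: zero importances in stable name order
  attrs$phi[] <- 0
  imp0 <- importance(attrs)
  expect_equal(imp0$feature, c("A", "B"))
  expect_true(all(imp0$overall == 0))
})

test_that("a dominant main effect is ranked first by the explained model", {
  firsts <- 0L
  for (seed in 1:10) {
    spec <- generator_spec(
      n_samples = 700,
      main_effects = c(LSBP = 2, Exs = 0.2, Sm = 0.2, Wt = 0.2),
      pair_effects = NULL, noise_scale = 0.3, seed = seed
    )
    ds <- encode(clean_table(generate(spec), quiet = TRUE))
    m <- train(build_base_dnn(34, seed = seed), ds,
               config = quick_config(seed = seed, max_epochs = 40))
    attrs <- compute_attributions(m, ds, rows = 1:20,
                                  n_background = 50,
                                  n_permutations = 10, seed = seed)
    firsts <- firsts + (importance(attrs)$feature[1] == "LSBP")
  }
  expect_gte(firsts, 9L)
})

test_that("interaction tables are symmetric, zero-diagonal, and null for additive models", {
  set.seed(33)
  bg <- matrix(rnorm(10 * 4), 10, 4,
               dimnames = list(NULL, c("a", "b", "c", "d")))
  rows <- matrix(rnorm(5 * 4), 5, 4,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  add_fn <- function(X) matrix(X[, 1] + 2 * X[, 2] - X[, 3]^2 + X[, 4],
                               ncol = 1)
  tbl <- interactions(add_fn, rows, bg, c("a", "b", "c", "d"))
  expect_lt(max(abs(tbl$index)), 1e-6)

  prod_fn <- function(X) matrix(X[, 1] * X[, 2] + 0.2 * X[, 3], ncol = 1)
  tbl2 <- interactions(prod_fn, rows, bg, c("a", "b", "c", "d"))
  M <- tbl2$index[, , 1]
  expect_equal(M, t(M), tolerance = 1e-10)
  expect_equal(diag(M), rep(0, 4), ignore_attr = TRUE)
  ij <- which(abs(M) == max(abs(M)), arr.ind = TRUE)[1, ]
  expect_setequal(unname(ij), c(1, 2))

  expect_error(interactions(prod_fn, rows, bg, c("a", "nope")),
               "unknown candidate")
})

test_that("select_order2 ranks pairs with deterministic tie-breaks", {
  # crafted table: (a,b) strength 3, (c,d) strength 2, (a,c) == (a,d)
  idx <- array(0, c(4, 4, 1),
               dimnames = list(c("a", "b", "c", "d"),
                               c("a", "b", "c", "d"), "class1"))
  set_pair <- function(arr, i, j, v) {
    arr[i, j, 1] <- v; arr[j, i, 1] <- v; arr
  }
  idx <- set_pair(idx, 1, 2, 3)
  idx <- set_pair(idx, 3, 4, 2)
  idx <- set_pair(idx, 1, 3, 1)
  idx <- set_pair(idx, 1, 4, 1)
  tbl <- structure(list(index = idx, candidates = c("a", "b", "c", "d")),
                   class = "interaction_table")
  sel <- select_order2(tbl, 4)
  expect_equal(paste(sel$feature1, sel$feature2),
               c("a b", "c d", "a c", "a d"))
  all6 <- select_order2(tbl, 6)
  expect_equal(nrow(all6), 6)
  expect_error(select_order2(tbl, 7), "exceeds")
})

test_that("force and dependence exports honor the additive identity", {
  f <- function(X) cbind(X[, 1] * X[, 2], X[, 3], -X[, 1], X[, 2]^2)
  set.seed(3)
  X <- matrix(rnorm(30 * 3), 30, 3,
              dimnames = list(NULL, c("Sm", "LSBP", "Exs")))
  ds <- structure(
    list(X = X, feature_names = colnames(X),
         risk = sample(0:3, 30, TRUE),
         occurrence = integer(30), scaler = NULL, schema = NULL),
    class = "encoded_dataset"
  )
  attrs <- compute_attributions(f, ds, rows = 1:6, n_background = 10,
                                n_permutations = 40, seed = 9)
  for (i in 1:6) {
    for (cls in attrs$classes) {
      rec <- force_data(attrs, i, cls)
      expect_equal(attr(rec, "y_base") + sum(rec$contribution),
                   attr(rec, "model_output"), tolerance = 1e-9)
      expect_true(all(diff(abs(rec$contribution)) <= 1e-12))
    }
  }
  expect_error(force_data(attrs, 99, "low"), "out of range")
  expect_error(force_data(attrs, 1, "nope"), "unknown class")

  dep <- dependence_data(attrs, "Sm", "LSBP", class = "low")
  expect_equal(nrow(dep), 6)
  expect_equal(dep$value, as.numeric(X[1:6, "Sm"]))
  expect_error(dependence_data(attrs, "nope", "Sm"), "unknown feature")
})

test_that("a planted positive interaction yields positive attributions at high values", {
  # model with a positive Sm effect on the last output: a current smoker
  # (high positive encoded value) must receive positive credit
  f <- function(X) cbind(0 * X[, 1], X[, 1] * X[, 2], 2 * X[, 1], X[, 1])
  X <- matrix(c(2, 1.5, 0, 0.5), 2, 2,
              dimnames = list(NULL, c("Sm", "LSBP")))
  bg <- matrix(0, 4, 2, dimnames = list(NULL, c("Sm", "LSBP")))
  phi <- exact_shapley(f, X[1, ], bg)
  expect_gt(phi["Sm", 3], 0)
  expect_gt(phi["Sm", 4], 0)
})
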