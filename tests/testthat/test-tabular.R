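test_that("cleaning fills Ys for never-smokers and imputes medians", {
  tab <- small_table(n = 100, seed = 4)
  raw <- tab
  raw$Ys[raw$Sm == 0][1] <- NA          # undefined for a never-smoker
  miss_row <- 7
  lsbp_true <- raw$LSBP[miss_row]
  raw$LSBP[miss_row] <- NA
  cleaned <- clean_table(raw, quiet = TRUE)
  expect_equal(nrow(cleaned), 100)
  expect_true(all(cleaned$Ys[cleaned$Sm == 0] == 0))
  expect_equal(cleaned$LSBP[miss_row],
               median(raw$LSBP[-miss_row]))
  expect_false(anyNA(as.data.frame(cleaned)))
})

test_that("cleaning is idempotent and drops out-of-code categoricals", {
  tab <- small_table(n = 80, seed = 6)
  once <- clean_table(tab, quiet = TRUE)
  twice <- clean_table(once, quiet = TRUE)
  expect_equal(as.data.frame(twice), as.data.frame(once))

  bad <- tab
  bad$Sm[3] <- 9
  bad$risk[5] <- NA
  expect_message(out <- clean_table(bad), "dropped 1 row")
  expect_equal(nrow(out), 78)

  allbad <- tab
  allbad$Exs <- 5
  expect_error(clean_table(allbad, quiet = TRUE), "every row")
})

test_that("encoding standardizes continuous and passes categoricals through", {
  tab <- clean_table(small_table(n = 200, seed = 8), quiet = TRUE)
  ds <- encode(tab)
  sch <- default_schema()
  for (j in seq_along(ds$feature_names)) {
    nm <- ds$feature_names[j]
    kind <- sch$kind[match(nm, sch$name)]
    if (kind == "continuous") {
      expect_lt(abs(mean(ds$X[, j])), 1e-6)
      expect_lt(abs(sd(ds$X[, j]) - 1), 1e-6)
    } else {
      expect_equal(ds$X[, j], as.numeric(tab[[nm]]))
    }
  }
  # ordinal pass-through: code 3 encodes as 3.0
  expect_true(all(ds$X[, "Edu"] %in% 1:5))
})

test_that("a fitted scaler reused on new data leaks nothing and inverts", {
  tab <- clean_table(small_table(n = 150, seed = 10), quiet = TRUE)
  ds <- encode(tab)
  sp <- split_dataset(ds, test_fraction = 0.2, seed = 1)
  # re-encode the test rows with the train-fitted scaler
  tr_tab <- tab[sp$train_idx, ]
  te_tab <- tab[sp$test_idx, ]
  ds_tr <- encode(tr_tab)
  ds_te <- encode(te_tab, scaler = ds_tr$scaler)
  mu <- ds_tr$scaler$mean[ds_tr$scaler$feature == "LSBP"]
  sdv <- ds_tr$scaler$sd[ds_tr$scaler$feature == "LSBP"]
  expect_equal(ds_te$X[, "LSBP"], (te_tab$LSBP - mu) / sdv)

  dec <- decode(ds_tr)
  expect_equal(dec$LSBP, tr_tab$LSBP, tolerance = 1e-9)
  expect_equal(dec$Edu, as.numeric(tr_tab$Edu))
})

test_that("zero-variance continuous columns are clamped with a warning", {
  tab <- clean_table(small_table(n = 50, seed = 12), quiet = TRUE)
  tab$TG <- 1.2
  expect_warning(ds <- encode(tab), "zero-variance")
  expect_true(all(ds$X[, "TG"] == 0))
})

test_that("stratified split hits per-class counts and partitions the data", {
  n <- 20531
  counts <- c(7221, 5868, 5475, 1967)
  risk <- rep(0:3, counts)
  ds <- structure(
    list(X = matrix(rnorm(2 * n), n, 2,
                    dimnames = list(NULL, c("a", "b"))),
         feature_names = c("a", "b"), risk = risk,
         occurrence = as.integer(risk == 3),
         scaler = NULL, schema = NULL),
    class = "encoded_dataset"
  )
  sp <- split_dataset(ds, test_fraction = 0.15, seed = 2)
  te_counts <- as.integer(table(factor(sp$test$risk, levels = 0:3)))
  expect_true(all(abs(te_counts - c(1083, 880, 821, 295)) <= 2))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(n))

  sp2 <- split_dataset(ds, test_fraction = 0.15, seed = 2)
  expect_identical(sp$test_idx, sp2$test_idx)

  folds <- split_folds(sp)
  expect_equal(nrow(folds), n)
  expect_equal(sum(folds$fold == "test"), length(sp$test_idx))
})

test_that("balanced toy splits exactly and tiny classes refuse stratification", {
  risk <- rep(c(0L, 1L), each = 20)
  ds <- structure(
    list(X = matrix(0, 40, 1, dimnames = list(NULL, "a")),
         feature_names = "a", risk = risk,
         occurrence = integer(40), scaler = NULL, schema = NULL),
    class = "encoded_dataset"
  )
  sp <- split_dataset(ds, test_fraction = 0.5, seed = 3)
  expect_equal(as.integer(table(sp$test$risk)), c(10, 10))

  ds$risk[1:39] <- 0L
  ds$risk[40] <- 1L
  expect_error(split_dataset(ds, 0.5, seed = 1), "fewer than 2")
})
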