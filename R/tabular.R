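#' Clean a labeled screening table
#'
#' Applies the package's cleaning rules: rows with a missing risk label are
#' dropped; a missing years-of-smoking value is set to 0 for never-smokers
#' (it is undefined for them); any other missing continuous value is
#' imputed by its column median; rows whose categorical values fall outside
#' the schema's code set are dropped, with the count reported via
#' `message()`. Cleaning is idempotent: a table that already satisfies the
#' schema is returned unchanged.
#'
#' @param table A labeled table (tibble with schema columns + `risk`,
#'   `occurrence`).
#' @param schema Schema tibble.
#' @param quiet Suppress the dropped-row message.
#' @return The cleaned tibble, same column order.
#' @export
clean_table <- function(table, schema = default_schema(), quiet = FALSE) {
  df <- tibble::as_tibble(table)
  df <- df[!is.na(df$risk), , drop = FALSE]

  if (all(c("Ys", "Sm") %in% names(df))) {
    fix <- is.na(df$Ys) & !is.na(df$Sm) & df$Sm == 0
    df$Ys[fix] <- 0
  }

  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (schema$kind[i] == "continuous") {
      miss <- is.na(df[[nm]])
      if (any(miss)) {
        med <- stats::median(df[[nm]], na.rm = TRUE)
        df[[nm]][miss] <- med
      }
    } else {
      bad <- is.na(df[[nm]]) | !(df[[nm]] %in% schema$codes[[i]])
      keep <- keep & !bad
    }
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet) {
    message("clean_table: dropped ", n_dropped,
            " row(s) with out-of-code categorical values")
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) stop("cleaning removed every row", call. = FALSE)
  df$risk <- as.integer(df$risk)
  df$occurrence <- as.integer(df$risk == 3L)
  attr(df, "schema") <- schema
  class(df) <- unique(c("labeled_table", class(df)))
  df
}

#' Encode a clean table into a model-ready numeric dataset
#'
#' Categorical (binary/ordinal) features pass through as their integer
#' codes — the models take one input neuron per feature, so no one-hot
#' expansion — while continuous features are standardized to zero mean and
#' unit variance. The standardization moments are fitted on the data at
#' hand when `scaler = NULL` (the training split) and reused verbatim when
#' a fitted scaler is supplied (the test split), so no test information
#' leaks into the encoding.
#'
#' @param table Clean labeled table.
#' @param schema Schema tibble.
#' @param scaler Optional fitted scaler (from a previous `encode()` call);
#'   when `NULL` the scaler is fitted here.
#' @param features Optional character vector restricting/ordering the
#'   encoded columns (defaults to full schema order).
#' @return An `encoded_dataset`: list with `X` (numeric matrix),
#'   `feature_names`, `risk`, `occurrence`, `scaler` (tibble of per-column
#'   mean/sd, sd of categorical columns recorded as NA), and `schema`.
#' @export
encode <- function(table, schema = default_schema(), scaler = NULL,
                   features = NULL) {
  features <- features %||% schema$name
  stopifnot(all(features %in% schema$name))
  n <- nrow(table)
  X <- matrix(0, n, length(features),
              dimnames = list(NULL, features))
  if (is.null(scaler)) {
    scaler <- fit_scaler(table, schema, features)
  }
  for (j in seq_along(features)) {
    nm <- features[j]
    v <- as.numeric(table[[nm]])
    row <- scaler[scaler$feature == nm, ]
    if (!is.na(row$sd)) {
      v <- (v - row$mean) / row$sd
    }
    X[, j] <- v
  }
  if (any(!is.finite(X))) stop("non-finite values after encoding",
                               call. = FALSE)
  structure(
    list(
      X = X, feature_names = features,
      risk = as.integer(table$risk),
      occurrence = as.integer(table$occurrence),
      scaler = scaler, schema = schema
    ),
    class = "encoded_dataset"
  )
}

fit_scaler <- function(table, schema, features) {
  rows <- purrr::map(features, function(nm) {
    kind <- schema$kind[match(nm, schema$name)]
    if (kind == "continuous") {
      v <- as.numeric(table[[nm]])
      s <- stats::sd(v)
      if (!is.finite(s) || s < 1e-12) {
        warning("zero-variance continuous column ", nm,
                "; sd clamped to 1", call. = FALSE)
        s <- 1
      }
      tibble::tibble(feature = nm, mean = mean(v), sd = s)
    } else {
      tibble::tibble(feature = nm, mean = 0, sd = NA_real_)
    }
  })
  dplyr::bind_rows(rows)
}

#' Invert an encoding back to the original feature scale
#'
#' @param dataset An `encoded_dataset`.
#' @return A tibble with the original-scale feature columns plus `risk`
#'   and `occurrence`.
#' @export
decode <- function(dataset) {
  stopifnot(inherits(dataset, "encoded_dataset"))
  X <- dataset$X
  out <- purrr::map(seq_along(dataset$feature_names), function(j) {
    nm <- dataset$feature_names[j]
    row <- dataset$scaler[dataset$scaler$feature == nm, ]
    v <- X[, j]
    if (!is.na(row$sd)) v <- v * row$sd + row$mean
    v
  })
  names(out) <- dataset$feature_names
  out <- tibble::as_tibble(out)
  out$risk <- dataset$risk
  out$occurrence <- dataset$occurrence
  out
}

#' Stratified train/test split of an encoded dataset
#'
#' Splits by the risk label so each class contributes
#' `round(class_count * test_fraction)` rows (within one) to the test set;
#' deterministic for a fixed seed. The default fraction 0.15 matches a
#' screening study that holds out about 15% of each state for testing.
#'
#' @param dataset An `encoded_dataset`.
#' @param test_fraction Fraction of each class held out, in (0, 1).
#' @param stratify Stratify by risk label (default TRUE).
#' @param seed Integer seed.
#' @return List with `train` and `test` (both `encoded_dataset`s carrying
#'   the same scaler) and the integer index vectors `train_idx`,
#'   `test_idx`.
#' @export
split_dataset <- function(dataset, test_fraction = 0.15, stratify = TRUE,
                          seed = 1L) {
  stopifnot(inherits(dataset, "encoded_dataset"),
            test_fraction > 0, test_fraction < 1)
  n <- nrow(dataset$X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (stratify) {
    counts <- table(dataset$risk)
    if (any(counts < 2)) {
      stop("cannot stratify: a class has fewer than 2 members",
           call. = FALSE)
    }
    test_idx <- integer(0)
    for (cls in as.integer(names(counts))) {
      idx <- which(dataset$risk == cls)
      k <- round(length(idx) * test_fraction)
      k <- max(1L, min(k, length(idx) - 1L))
      test_idx <- c(test_idx, sample(idx, k))
    }
  } else {
    k <- round(n * test_fraction)
    test_idx <- sample.int(n, k)
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  list(
    train = subset_dataset(dataset, train_idx),
    test = subset_dataset(dataset, test_idx),
    train_idx = train_idx,
    test_idx = test_idx
  )
}

subset_dataset <- function(dataset, idx) {
  structure(
    list(
      X = dataset$X[idx, , drop = FALSE],
      feature_names = dataset$feature_names,
      risk = dataset$risk[idx],
      occurrence = dataset$occurrence[idx],
      scaler = dataset$scaler, schema = dataset$schema
    ),
    class = "encoded_dataset"
  )
}

#' Export split indices as a two-column fold table
#'
#' @param split A list from [split_dataset()].
#' @return Tibble with `row_id` and `fold` ("train"/"test").
#' @export
split_folds <- function(split) {
  dplyr::arrange(
    tibble::tibble(
      row_id = c(split$train_idx, split$test_idx),
      fold = rep(c("train", "test"),
                 c(length(split$train_idx), length(split$test_idx)))
    ),
    .data$row_id
  )
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat("<encoded_dataset> ", nrow(x$X), " samples x ", ncol(x$X),
      " features\n", sep = "")
  cat("  risk counts:",
      paste(table(factor(x$risk, levels = 0:3)), collapse = ":"), "\n")
  invisible(x)
}
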