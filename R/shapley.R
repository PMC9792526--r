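# Shapley attribution with a background set. The coalition value v(S) of
# a feature subset S is the model output with features in S taken from
# the explained row and all other *player* features replaced by
# background rows, averaged over the background. Attributions are
# computed on the model's logits (pre-softmax outputs).

# model_fn: function(matrix) -> matrix (n x C) of outputs
eval_coalitions <- function(model_fn, x, background, players, masks) {
  # masks: list of logical vectors over players (TRUE = take from x)
  bg <- as.matrix(background)
  n_bg <- nrow(bg)
  rows <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    B <- bg
    on <- players[masks[[i]]]
    if (length(on) > 0) B[, on] <- matrix(x[on], n_bg, length(on),
                                          byrow = TRUE)
    rows[[i]] <- B
  }
  big <- do.call(rbind, rows)
  out <- model_fn(big)
  if (!is.matrix(out)) out <- matrix(out, ncol = 1)
  # average over background per coalition
  grp <- rep(seq_along(masks), each = n_bg)
  V <- rowsum(out, grp) / n_bg
  V # one row per coalition, one column per class
}

#' Exact Shapley attributions by coalition enumeration
#'
#' Computes, for every feature in `features`, its exact Shapley value
#' `phi_j = sum_{S subset F\\{j}} |S|!(|F|-|S|-1)!/|F|! [v(S u {j}) - v(S)]`
#' where the coalition value `v(S)` is the model output with the features
#' in `S` fixed at the explained row's values and the remaining player
#' features averaged over the background rows. Features outside
#' `features` are held at the explained row's values throughout. The
#' result satisfies the efficiency identity exactly: the attributions sum
#' to `v(F) - v(empty)` per output class. Enumeration is limited to 12
#' players.
#'
#' @param model_fn Function mapping an input matrix to an n x C output
#'   matrix (use logits for deep models), or a `strokeqi_model` (its
#'   logits are used).
#' @param x A single encoded row (numeric vector).
#' @param background Matrix of background rows on the same encoding.
#' @param features Integer indices (or names matching `names(x)`) of the
#'   player features; defaults to all columns.
#' @return Matrix `phi` of dimension (players x classes) with attribute
#'   `y_base` (the per-class value of the empty coalition) and
#'   `model_output` (the per-class value of the full coalition).
#' @examples
#' f <- function(X) matrix(X[, 1] * X[, 2] + X[, 3], ncol = 1)
#' exact_shapley(f, c(1, 1, 1), matrix(0, 1, 3)) # 0.5, 0.5, 1.0
#' @export
exact_shapley <- function(model_fn, x, background,
                          features = seq_along(x)) {
  model_fn <- as_model_fn(model_fn)
  if (is.character(features)) features <- match(features, names(x))
  m <- length(features)
  if (m > 12) stop("exact enumeration limited to 12 features",
                   call. = FALSE)
  feat_names <- if (!is.null(names(x))) names(x)[features] else
    paste0("f", features)
  x <- as.numeric(x)
  masks <- all_masks(m)
  V <- eval_coalitions(model_fn, x, background, features, masks)
  C <- ncol(V)
  sizes <- purrr::map_int(masks, sum)
  w <- shapley_weights(m)
  key <- purrr::map_chr(masks, mask_key)
  lookup <- stats::setNames(seq_along(masks), key)

  phi <- matrix(0, m, C)
  for (j in seq_len(m)) {
    for (i in seq_along(masks)) {
      if (masks[[i]][j]) next
      s <- sizes[i]
      with_j <- masks[[i]]; with_j[j] <- TRUE
      iw <- lookup[[mask_key(with_j)]]
      phi[j, ] <- phi[j, ] + w[s + 1] * (V[iw, ] - V[i, ])
    }
  }
  empty <- lookup[[mask_key(rep(FALSE, m))]]
  full <- lookup[[mask_key(rep(TRUE, m))]]
  rownames(phi) <- feat_names
  attr(phi, "y_base") <- V[empty, ]
  attr(phi, "model_output") <- V[full, ]
  phi
}

all_masks <- function(m) {
  purrr::map(0:(2^m - 1), function(b) {
    as.logical(bitwAnd(bitwShiftR(b, 0:(m - 1)), 1L))
  })
}

mask_key <- function(mask) paste(as.integer(mask), collapse = "")

# w[s+1] = s!(m-s-1)!/m!
shapley_weights <- function(m) {
  s <- 0:(m - 1)
  exp(lfactorial(s) + lfactorial(m - s - 1) - lfactorial(m))
}

# probability-weighted risk level of a 4-class model as a 1-column output
expected_class_fn <- function(model) {
  if (is.function(model)) {
    base <- model
    return(function(X) {
      out <- base(X)
      if (NCOL(out) == 1) return(matrix(out, ncol = 1))
      matrix(softmax_rows(out) %*% (seq_len(ncol(out)) - 1), ncol = 1)
    })
  }
  if (inherits(model, "mmoe_model")) {
    return(function(X) {
      matrix(predict(model, X, type = "prob")$risk %*% 0:3, ncol = 1)
    })
  }
  function(X) {
    p <- predict(model, X, type = "prob")
    if (!is.matrix(p)) return(matrix(p, ncol = 1))
    matrix(p %*% (seq_len(ncol(p)) - 1), ncol = 1)
  }
}

as_model_fn <- function(model_fn) {
  if (inherits(model_fn, "strokeqi_model")) {
    model <- model_fn
    if (inherits(model, "mmoe_model")) {
      function(X) predict(model, X, type = "logits")$risk
    } else {
      function(X) {
        out <- predict(model, X, type = "logits")
        if (!is.matrix(out)) matrix(out, ncol = 1) else out
      }
    }
  } else {
    model_fn
  }
}

#' Permutation-sampling Shapley estimate
#'
#' Estimates Shapley values by averaging marginal contributions along
#' random feature orderings; each permutation walks features into the
#' coalition in order and credits each feature with the change in the
#' background-averaged model output. The estimator is unbiased for the
#' exact value; after sampling, the efficiency residual
#' `(v(F) - v(empty)) - sum(phi)` is distributed across features
#' proportionally to `|phi_j|`, so the additive identity holds to
#' numerical precision. Reproducible under `seed`.
#'
#' @inheritParams exact_shapley
#' @param n_permutations Number of random orderings (>= 1).
#' @param seed Integer seed.
#' @return As [exact_shapley()].
#' @export
sampled_shapley <- function(model_fn, x, background, n_permutations = 200,
                            seed = 1L, features = seq_along(x)) {
  stopifnot(n_permutations >= 1)
  model_fn <- as_model_fn(model_fn)
  if (is.character(features)) features <- match(features, names(x))
  feat_names <- if (!is.null(names(x))) names(x)[features] else
    paste0("f", features)
  x <- as.numeric(x)
  m <- length(features)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  base_full <- eval_coalitions(model_fn, x, background, features,
                               list(rep(FALSE, m), rep(TRUE, m)))
  C <- ncol(base_full)
  y_base <- base_full[1, ]
  y_full <- base_full[2, ]

  phi <- matrix(0, m, C)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(m)
    # prefix coalitions: empty, then adding ord[1], ord[2], ...
    masks <- vector("list", m + 1)
    cur <- rep(FALSE, m)
    masks[[1]] <- cur
    for (t in seq_len(m)) {
      cur[ord[t]] <- TRUE
      masks[[t + 1]] <- cur
    }
    V <- eval_coalitions(model_fn, x, background, features, masks)
    for (t in seq_len(m)) {
      phi[ord[t], ] <- phi[ord[t], ] + (V[t + 1, ] - V[t, ])
    }
  }
  phi <- phi / n_permutations

  # enforce efficiency: spread the residual proportionally to |phi|
  for (c in seq_len(C)) {
    res <- (y_full[c] - y_base[c]) - sum(phi[, c])
    denom <- sum(abs(phi[, c]))
    if (denom > 1e-12) {
      phi[, c] <- phi[, c] + res * abs(phi[, c]) / denom
    } else {
      phi[, c] <- phi[, c] + res / m
    }
  }
  rownames(phi) <- feat_names
  attr(phi, "y_base") <- y_base
  attr(phi, "model_output") <- y_full
  phi
}

#' Attribution set over a dataset
#'
#' Runs [sampled_shapley()] (or the exact enumerator when the player
#' count allows and `exact = TRUE`) on each requested row and collects
#' the per-sample, per-feature, per-class attributions.
#'
#' @param model A fitted model or model function.
#' @param dataset An `encoded_dataset` (rows to explain).
#' @param background Matrix of background rows; defaults to up to
#'   `n_background` rows sampled from `dataset` under `seed`.
#' @param rows Integer indices of the rows to explain (default: all).
#' @param n_permutations Permutations per row for the sampled estimator.
#' @param n_background Background size when sampling from `dataset`
#'   (default 100).
#' @param exact Use exact enumeration (player count must be <= 12).
#' @param seed Integer seed.
#' @return An `attribution_set`: list with `phi` (n x d x C array),
#'   `y_base` (per class), `model_output` (n x C), `feature_names`,
#'   `classes`, `rows`.
#' @export
compute_attributions <- function(model, dataset, background = NULL,
                                 rows = NULL,
                                 n_permutations = 30,
                                 n_background = 100,
                                 exact = FALSE, seed = 1L) {
  X <- if (inherits(dataset, "encoded_dataset")) dataset$X else
    as.matrix(dataset)
  feature_names <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  rows <- rows %||% seq_len(nrow(X))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (is.null(background)) {
    bg_idx <- sample.int(nrow(X), min(n_background, nrow(X)))
    background <- X[bg_idx, , drop = FALSE]
  }
  model_fn <- as_model_fn(model)
  first <- model_fn(X[1, , drop = FALSE])
  C <- NCOL(first)
  classes <- if (C == 4) risk_levels else paste0("class", seq_len(C))

  d <- ncol(X)
  phi <- array(0, c(length(rows), d, C),
               dimnames = list(NULL, feature_names, classes))
  outs <- matrix(0, length(rows), C)
  for (i in seq_along(rows)) {
    x <- X[rows[i], ]
    p <- if (exact) {
      exact_shapley(model_fn, x, background)
    } else {
      sampled_shapley(model_fn, x, background,
                      n_permutations = n_permutations,
                      seed = seed + i)
    }
    phi[i, , ] <- p
    outs[i, ] <- attr(p, "model_output")
    y_base <- attr(p, "y_base")
  }
  structure(
    list(phi = phi, y_base = y_base, model_output = outs,
         feature_names = feature_names, classes = classes, rows = rows,
         X = X[rows, , drop = FALSE]),
    class = "attribution_set"
  )
}

#' Tidy an attribution set into long format
#'
#' @param x An `attribution_set`.
#' @param ... Unused.
#' @return Tibble with columns `sample`, `feature`, `class`, `phi`.
#' @export
tidy.attribution_set <- function(x, ...) {
  d <- dim(x$phi)
  tibble::tibble(
    sample = rep(x$rows, times = d[2] * d[3]),
    feature = rep(rep(x$feature_names, each = d[1]), times = d[3]),
    class = rep(x$classes, each = d[1] * d[2]),
    phi = as.numeric(x$phi)
  )
}

#' Feature importance from an attribution set
#'
#' Per class, the importance of a feature is the mean of its absolute
#' attributions over the explained samples; the overall importance is the
#' unweighted mean over classes. Rows are sorted by descending overall
#' importance, ties broken by feature name.
#'
#' @param attrs An `attribution_set`.
#' @return Tibble with `feature`, one column per class, `overall`,
#'   `rank`.
#' @export
importance <- function(attrs) {
  stopifnot(inherits(attrs, "attribution_set"))
  per_class <- apply(abs(attrs$phi), c(2, 3), mean)
  overall <- unname(rowMeans(per_class))
  out <- tibble::as_tibble(per_class)
  out <- dplyr::mutate(out, feature = attrs$feature_names,
                       overall = overall, .before = 1)
  out <- dplyr::arrange(out, dplyr::desc(.data$overall), .data$feature)
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Pairwise Shapley interaction table
#'
#' Computes the exact Shapley interaction index among the candidate
#' features: for a pair (j, k),
#' `I_jk = sum_{S subset F\\{j,k}} |S|!(|F|-|S|-2)!/(2(|F|-1)!) *
#' [v(S u {j,k}) - v(S u {j}) - v(S u {k}) + v(S)]`,
#' averaged over the explained rows. Candidates are the players;
#' non-candidate features stay at each explained row's values. The table
#' is symmetric with a zero diagonal, one matrix per output class.
#'
#' For screening with a four-state classifier, `output = "expected_class"`
#' scores interactions on the probability-weighted risk level
#' `sum_c c * p_c(x)` instead of the per-class logits. The expected level
#' is approximately linear in the underlying severity, so the curvature
#' of the class logits — which manufactures spurious interactions between
#' any two strong features — largely cancels, making the ranking far more
#' robust; per-class logit tables remain available as the default.
#'
#' @param model_fn Model function or fitted model (logits are used).
#' @param rows Matrix of rows to explain (encoded scale).
#' @param background Background matrix.
#' @param candidates Integer indices or column names of the candidate
#'   pool (at most 12).
#' @param output `"logits"` (one table per class) or `"expected_class"`
#'   (single table on the expected risk level; fitted 4-class models
#'   only).
#' @return An `interaction_table`: list with `index` (p x p x C array,
#'   candidate names on both axes) and `candidates`.
#' @export
interactions <- function(model_fn, rows, background, candidates,
                         output = c("logits", "expected_class")) {
  output <- match.arg(output)
  model_fn <- if (output == "expected_class") {
    expected_class_fn(model_fn)
  } else {
    as_model_fn(model_fn)
  }
  rows <- as.matrix(rows)
  if (is.character(candidates)) {
    idx <- match(candidates, colnames(rows))
    if (anyNA(idx)) stop("unknown candidate feature(s): ",
                         paste(candidates[is.na(idx)], collapse = ", "),
                         call. = FALSE)
    candidates <- idx
  }
  p <- length(candidates)
  if (p > 12) stop("interaction enumeration limited to 12 candidates",
                   call. = FALSE)
  cand_names <- colnames(rows)[candidates] %||% paste0("f", candidates)
  masks <- all_masks(p)
  sizes <- purrr::map_int(masks, sum)
  key <- purrr::map_chr(masks, mask_key)
  lookup <- stats::setNames(seq_along(masks), key)
  # weight for |S| in the interaction index
  wt <- function(s) {
    exp(lfactorial(s) + lfactorial(p - s - 2) - lfactorial(p - 1)) / 2
  }

  # batched coalition values: V[row, coalition, class], averaged over the
  # background, computed one coalition at a time over all rows at once
  bg <- as.matrix(background)
  n_bg <- nrow(bg)
  n_rows <- nrow(rows)
  base <- bg[rep(seq_len(n_bg), times = n_rows), , drop = FALSE]
  row_of <- rep(seq_len(n_rows), each = n_bg)
  C <- NCOL(as_model_fn(model_fn)(rows[1, , drop = FALSE]))
  V <- array(0, c(n_rows, length(masks), C))
  for (i in seq_along(masks)) {
    B <- base
    on <- candidates[masks[[i]]]
    if (length(on) > 0) {
      B[, on] <- rows[row_of, on, drop = FALSE]
    }
    out <- model_fn(B)
    if (!is.matrix(out)) out <- matrix(out, ncol = 1)
    V[, i, ] <- rowsum(out, row_of) / n_bg
  }

  acc <- array(0, c(p, p, C))
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) {
      I_jk <- matrix(0, n_rows, C)
      for (i in seq_along(masks)) {
        mk <- masks[[i]]
        if (mk[j] || mk[k]) next
        s <- sizes[i]
        mj <- mk; mj[j] <- TRUE
        mk2 <- mk; mk2[k] <- TRUE
        mjk <- mj; mjk[k] <- TRUE
        delta <- V[, lookup[[mask_key(mjk)]], , drop = FALSE] -
          V[, lookup[[mask_key(mj)]], , drop = FALSE] -
          V[, lookup[[mask_key(mk2)]], , drop = FALSE] +
          V[, i, , drop = FALSE]
        I_jk <- I_jk + wt(s) * matrix(delta, n_rows, C)
      }
      avg <- colMeans(I_jk)
      acc[j, k, ] <- avg
      acc[k, j, ] <- avg
    }
  }
  dimnames(acc) <- list(cand_names, cand_names,
                        if (dim(acc)[3] == 4) risk_levels else
                          paste0("class", seq_len(dim(acc)[3])))
  structure(list(index = acc, candidates = cand_names),
            class = "interaction_table")
}

#' Seed-averaged interaction screening
#'
#' The interaction profile of a single trained network carries
#' initialization-specific ghosts; averaging the absolute interaction
#' index over a few independently initialized fits of the same
#' architecture stabilizes the ranking. Returns an `interaction_table`
#' whose entries are the mean |index| across models (nonnegative).
#'
#' @param models List of fitted models (or model functions).
#' @param rows,background,candidates,output As in [interactions()];
#'   `output` defaults to `"expected_class"` here, the robust screening
#'   statistic.
#' @return An `interaction_table`.
#' @export
screen_interactions <- function(models, rows, background, candidates,
                                output = "expected_class") {
  stopifnot(length(models) >= 1)
  tables <- purrr::map(models, function(m) {
    interactions(m, rows, background, candidates, output = output)
  })
  acc <- abs(tables[[1]]$index)
  if (length(tables) > 1) {
    for (i in 2:length(tables)) acc <- acc + abs(tables[[i]]$index)
  }
  out <- tables[[1]]
  out$index <- acc / length(tables)
  out
}

#' Tidy an interaction table
#'
#' @param x An `interaction_table`.
#' @param ... Unused.
#' @return Tibble with `feature1`, `feature2`, `class`, `interaction`
#'   (each unordered pair once).
#' @export
tidy.interaction_table <- function(x, ...) {
  p <- length(x$candidates)
  classes <- dimnames(x$index)[[3]]
  out <- list()
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) {
      out[[length(out) + 1]] <- tibble::tibble(
        feature1 = pmin(x$candidates[j], x$candidates[k]),
        feature2 = pmax(x$candidates[j], x$candidates[k]),
        class = classes,
        interaction = x$index[j, k, ]
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Select order-2 feature pairs by interaction strength
#'
#' Ranks the candidate pairs by the absolute Shapley interaction index
#' summed over the output classes and returns the strongest `n_pairs`;
#' ties are broken by pair name. The dependence spread (`dependency`,
#' the share of a feature's attribution variance explained by its
#' partner's value) is reported alongside when an attribution set and
#' its feature values are supplied, but does not enter the ranking.
#'
#' @param inter An `interaction_table`.
#' @param n_pairs Number of pairs to return.
#' @param attrs Optional `attribution_set` (with `$X`) used to compute
#'   the reported dependency values.
#' @return Tibble with `feature1`, `feature2`, `strength`, `rank` (and
#'   `dependency` when available).
#' @export
select_order2 <- function(inter, n_pairs, attrs = NULL) {
  stopifnot(inherits(inter, "interaction_table"), n_pairs >= 1)
  long <- tidy(inter)
  ranked <- long |>
    dplyr::group_by(.data$feature1, .data$feature2) |>
    dplyr::summarise(strength = sum(abs(.data$interaction)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$strength), .data$feature1,
                   .data$feature2)
  if (n_pairs > nrow(ranked)) {
    stop("n_pairs exceeds the ", nrow(ranked), " available pairs",
         call. = FALSE)
  }
  out <- dplyr::mutate(head(ranked, n_pairs),
                       rank = dplyr::row_number())
  if (!is.null(attrs)) {
    out$dependency <- purrr::map2_dbl(out$feature1, out$feature2,
                                      function(a, b) {
                                        dependency_value(attrs, a, b)
                                      })
  }
  out
}

# share of variance of phi_a (summed over classes) explained by x_b
dependency_value <- function(attrs, feature_a, feature_b) {
  ja <- match(feature_a, attrs$feature_names)
  jb <- match(feature_b, attrs$feature_names)
  if (is.na(ja) || is.na(jb)) return(NA_real_)
  phi_a <- rowSums(attrs$phi[, ja, , drop = FALSE])
  xb <- attrs$X[, jb]
  if (stats::var(phi_a) < 1e-12 || stats::var(xb) < 1e-12) return(0)
  summary(stats::lm(phi_a ~ xb))$r.squared
}

#' Force-plot data for one sample and class
#'
#' @param attrs An `attribution_set`.
#' @param sample Position within the explained rows.
#' @param class Class name or 1-based index.
#' @return A `force_record`: tibble of `(feature, value, contribution)`
#'   sorted by `|contribution|` descending, with `y_base`,
#'   `model_output`, `sample` and `state` attached as attributes; the
#'   contributions satisfy `y_base + sum(contribution) = model_output`.
#' @export
force_data <- function(attrs, sample, class) {
  stopifnot(inherits(attrs, "attribution_set"))
  if (is.character(class)) class <- match(class, attrs$classes)
  if (is.na(class) || class < 1 || class > length(attrs$classes)) {
    stop("unknown class", call. = FALSE)
  }
  if (sample < 1 || sample > dim(attrs$phi)[1]) {
    stop("sample out of range", call. = FALSE)
  }
  contr <- attrs$phi[sample, , class]
  out <- tibble::tibble(
    feature = attrs$feature_names,
    value = as.numeric(attrs$X[sample, ]),
    contribution = as.numeric(contr)
  )
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$contribution)))
  attr(out, "y_base") <- attrs$y_base[class]
  attr(out, "model_output") <- attrs$model_output[sample, class]
  attr(out, "sample") <- attrs$rows[sample]
  attr(out, "state") <- attrs$classes[class]
  class(out) <- c("force_record", class(out))
  out
}

#' Dependence-plot data for one feature
#'
#' @param attrs An `attribution_set`.
#' @param feature Feature whose attribution is plotted.
#' @param color_feature Feature supplying the coloring value.
#' @param class Class name or index (default: the attack state when
#'   present, else the first class).
#' @return Tibble with one row per explained sample: `value` (the
#'   feature's encoded value), `phi` (its attribution for the class),
#'   `color_value`.
#' @export
dependence_data <- function(attrs, feature, color_feature,
                            class = NULL) {
  stopifnot(inherits(attrs, "attribution_set"))
  j <- match(feature, attrs$feature_names)
  jc <- match(color_feature, attrs$feature_names)
  if (is.na(j) || is.na(jc)) stop("unknown feature", call. = FALSE)
  class <- class %||% if ("attack" %in% attrs$classes) "attack" else
    attrs$classes[1]
  if (is.character(class)) class <- match(class, attrs$classes)
  tibble::tibble(
    sample = attrs$rows,
    value = as.numeric(attrs$X[, j]),
    phi = as.numeric(attrs$phi[, j, class]),
    color_value = as.numeric(attrs$X[, jc]),
    feature = feature,
    color_feature = color_feature,
    class = attrs$classes[class]
  )
}
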