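#' Run the full screening-to-models workflow on a labeled table
#'
#' Reproduces the study protocol end to end on a labeled table:
#' \enumerate{
#'   \item clean, encode and split the table (stratified by risk state);
#'   \item train the base DNN on all features;
#'   \item compute sampled Shapley attributions on a subsample and rank
#'     feature importance;
#'   \item take the top `n_candidates` features as the interaction
#'     candidate pool and screen all candidate pairs by the exact Shapley
#'     interaction index on the expected risk level, averaged over
#'     `n_screen_models` independently initialized base fits;
#'   \item select the strongest `n_pairs` order-2 pairs and train QIDeep
#'     on the top `n_top` features plus those pairs;
#'   \item assemble the two-objective MMOE (Expert 1 = single 11-unit
#'     hidden layer, Expert 2 = the QIDeep body) on the same features and
#'     train it jointly on occurrence + risk;
#'   \item evaluate every requested model on the held-out test set over
#'     `n_repeats` model seeds and aggregate mean/sd/CI.
#' }
#'
#' Baselines `rf`, `lr` and `gbdt` are delegated to randomForest,
#' nnet::multinom and xgboost (glue only) and are skipped with a message
#' when the package is not installed.
#'
#' @param table A labeled table (e.g. from [generate()]).
#' @param schema Schema tibble.
#' @param roster Character vector of models to evaluate; subset of
#'   `c("base_dnn", "qideep", "mmoe", "rf", "lr", "gbdt")`.
#' @param n_pairs Number of order-2 pairs for QIDeep/MMOE (default 3).
#' @param n_candidates Size of the interaction candidate pool (default 7).
#' @param n_screen_models Independently initialized base fits averaged by
#'   the interaction screening (default 3).
#' @param n_top Number of top-importance features fed to QIDeep/MMOE
#'   (default 20).
#' @param n_repeats Model seeds per roster entry (default 5).
#' @param test_fraction Held-out fraction (default 0.15).
#' @param n_explain Rows explained by the Shapley stage (default 40).
#' @param n_background Background rows for attribution (default 100).
#' @param n_permutations Permutations per explained row (default 20).
#' @param max_epochs,batch_size,patience Training controls passed to
#'   [train_config()].
#' @param seed Master seed.
#' @return A `pipeline_result` list: `importance`, `interaction`
#'   (tibble), `selected_pairs`, `top_features`, `models` (last fitted
#'   model per roster entry), `reports` (per-run `metrics_report`s),
#'   `aggregates` (tibble), `meta` (seed, sizes, per-stage wall time).
#' @export
run_pipeline <- function(table, schema = default_schema(),
                         roster = c("base_dnn", "qideep", "mmoe"),
                         n_pairs = 3, n_candidates = 7,
                         n_screen_models = 3, n_top = 20,
                         n_repeats = 5, test_fraction = 0.15,
                         n_explain = 40, n_background = 100,
                         n_permutations = 20,
                         max_epochs = 120, batch_size = 256,
                         patience = 20, seed = 1L) {
  roster <- match.arg(roster, c("base_dnn", "qideep", "mmoe", "rf",
                                "lr", "gbdt"), several.ok = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stage_times <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stage_times[[name]] <<- t1 - t0
    t0 <<- t1
  }

  table <- clean_table(table, schema, quiet = TRUE)
  ds <- encode(table, schema)
  sp <- split_dataset(ds, test_fraction = test_fraction, seed = seed)
  tick("prepare")

  cfg <- function(s) train_config(max_epochs = max_epochs,
                                  batch_size = batch_size,
                                  patience = patience, seed = s)
  base <- train(build_base_dnn(ncol(ds$X), seed = seed), sp$train,
                config = cfg(seed))
  tick("base_dnn")

  old <- .Random.seed_save()
  set.seed(seed)
  expl_rows <- sample.int(nrow(sp$train$X), min(n_explain,
                                                nrow(sp$train$X)))
  bg_rows <- sample.int(nrow(sp$train$X), min(n_background,
                                              nrow(sp$train$X)))
  .Random.seed_restore(old)
  background <- sp$train$X[bg_rows, , drop = FALSE]
  attrs <- compute_attributions(base, sp$train, background = background,
                                rows = expl_rows,
                                n_permutations = n_permutations,
                                seed = seed)
  imp <- importance(attrs)
  tick("shapley_importance")

  pool <- head(imp$feature, n_candidates)
  screen_models <- c(list(base), purrr::map(seq_len(n_screen_models - 1),
    function(i) {
      train(build_base_dnn(ncol(ds$X), seed = seed + 10L * i), sp$train,
            config = cfg(seed + 10L * i))
    }))
  inter <- screen_interactions(screen_models, attrs$X, background, pool)
  pairs_tbl <- select_order2(inter, n_pairs, attrs = attrs)
  tick("interaction_screening")

  top_features <- head(imp$feature, n_top)
  # keep pair members in the model input
  top_features <- union(top_features,
                        unique(c(pairs_tbl$feature1, pairs_tbl$feature2)))
  ds_top <- encode(table, schema, features = top_features)
  sp_top <- list(
    train = subset_dataset(ds_top, sp$train_idx),
    test = subset_dataset(ds_top, sp$test_idx)
  )
  qi <- qi_config(cbind(match(pairs_tbl$feature1, top_features),
                        match(pairs_tbl$feature2, top_features)))
  tick("prepare_top")

  reports <- list()
  models <- list()
  for (m in roster) {
    reports[[m]] <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      s <- seed + 1000L * r
      fit <- fit_roster_model(m, sp_top, sp, qi, cfg(s), s)
      models[[m]] <- fit$model
      reports[[m]][[r]] <- metrics_report(fit$true, fit$pred)
    }
  }
  aggregates <- dplyr::bind_rows(purrr::imap(reports, function(rr, m) {
    dplyr::mutate(aggregate_runs(rr), model = m, .before = 1)
  }))
  tick("train_evaluate")

  structure(
    list(
      importance = imp,
      interaction = tidy(inter),
      selected_pairs = pairs_tbl,
      top_features = top_features,
      base_model = base,
      models = models,
      reports = reports,
      aggregates = aggregates,
      split = sp,
      split_top = sp_top,
      meta = list(seed = seed, n_rows = nrow(table),
                  n_repeats = n_repeats, roster = roster,
                  stage_seconds = stage_times)
    ),
    class = "pipeline_result"
  )
}

fit_roster_model <- function(name, sp_top, sp_full, qi, config, seed) {
  test_top <- sp_top$test
  if (name == "base_dnn") {
    m <- train(build_base_dnn(ncol(sp_full$train$X), seed = seed),
               sp_full$train, config = config)
    return(list(model = m, true = sp_full$test$risk,
                pred = predict(m, sp_full$test, type = "class")))
  }
  if (name == "qideep") {
    m <- train(build_qideep(ncol(sp_top$train$X), qi, seed = seed),
               sp_top$train, config = config)
    return(list(model = m, true = test_top$risk,
                pred = predict(m, test_top, type = "class")))
  }
  if (name == "mmoe") {
    m <- train(build_mmoe(ncol(sp_top$train$X), qi, seed = seed),
               sp_top$train, config = config)
    return(list(model = m, true = test_top$risk,
                pred = predict(m, test_top, type = "class")$risk))
  }
  tr <- sp_full$train; te <- sp_full$test
  if (name == "rf") {
    if (!requireNamespace("randomForest", quietly = TRUE)) {
      stop("randomForest not installed", call. = FALSE)
    }
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    m <- randomForest::randomForest(
      x = tr$X, y = factor(tr$risk, levels = 0:3),
      ntree = 10 + (seed %% 10)
    )
    pred <- as.integer(as.character(predict(m, te$X)))
    return(list(model = m, true = te$risk, pred = pred))
  }
  if (name == "lr") {
    if (!requireNamespace("nnet", quietly = TRUE)) {
      stop("nnet not installed", call. = FALSE)
    }
    df <- data.frame(y = factor(tr$risk, levels = 0:3), tr$X,
                     check.names = TRUE)
    m <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 200)
    newdf <- data.frame(te$X, check.names = TRUE)
    pred <- as.integer(as.character(predict(m, newdf)))
    return(list(model = m, true = te$risk, pred = pred))
  }
  if (name == "gbdt") {
    if (!requireNamespace("xgboost", quietly = TRUE)) {
      stop("xgboost not installed", call. = FALSE)
    }
    m <- xgboost::xgboost(
      data = tr$X, label = tr$risk, objective = "multi:softmax",
      num_class = 4, nrounds = 50, verbose = 0,
      params = list(seed = seed)
    )
    pred <- as.integer(predict(m, te$X))
    return(list(model = m, true = te$risk, pred = pred))
  }
  stop("unknown roster entry: ", name, call. = FALSE)
}

#' Per-sample force and dependence exports
#'
#' For each requested test row, computes attributions for all four risk
#' states and returns one force record per state (efficiency check
#' attached), mirroring the per-state explainers of the analysis tool.
#'
#' @param model A fitted model.
#' @param dataset An `encoded_dataset` containing the samples.
#' @param sample_ids Row indices within `dataset`.
#' @param background Background matrix (default: up to 100 rows of
#'   `dataset`).
#' @param n_permutations Permutations per row.
#' @param seed Integer seed.
#' @return List with `attributions` (the `attribution_set`) and `force`
#'   (list, per sample, of four `force_record`s keyed by state).
#' @export
explain_samples <- function(model, dataset, sample_ids,
                            background = NULL, n_permutations = 30,
                            seed = 1L) {
  if (any(sample_ids < 1 | sample_ids > nrow(dataset$X))) {
    stop("unknown sample id", call. = FALSE)
  }
  attrs <- compute_attributions(model, dataset, background = background,
                                rows = sample_ids,
                                n_permutations = n_permutations,
                                seed = seed)
  force <- purrr::map(seq_along(sample_ids), function(i) {
    recs <- purrr::map(attrs$classes, ~ force_data(attrs, i, .x))
    names(recs) <- attrs$classes
    recs
  })
  names(force) <- paste0("sample_", sample_ids)
  list(attributions = attrs, force = force)
}

#' Write force records as JSON
#'
#' @param force The `force` element of [explain_samples()] output (or a
#'   single `force_record`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_force_json <- function(force, path) {
  serialize_rec <- function(rec) {
    list(
      sample = attr(rec, "sample"),
      state = attr(rec, "state"),
      y_base = attr(rec, "y_base"),
      model_output = attr(rec, "model_output"),
      efficiency_gap = attr(rec, "model_output") -
        attr(rec, "y_base") - sum(rec$contribution),
      contributions = as.data.frame(tibble::as_tibble(rec))
    )
  }
  payload <- if (inherits(force, "force_record")) {
    serialize_rec(force)
  } else {
    purrr::map(force, function(sample) purrr::map(sample, serialize_rec))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$meta$n_rows, " rows, roster: ",
      paste(x$meta$roster, collapse = ", "), "\n", sep = "")
  cat("  selected pairs: ",
      paste(pair_label(x$selected_pairs$feature1,
                       x$selected_pairs$feature2), collapse = " "),
      "\n", sep = "")
  acc <- dplyr::filter(x$aggregates, .data$metric == "accuracy")
  for (i in seq_len(nrow(acc))) {
    cat(sprintf("  %-9s accuracy %.2f%% +/- %.3f\n", acc$model[i],
                acc$mean[i], acc$sd[i]))
  }
  invisible(x)
}
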