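#' Specification for the synthetic-data generator
#'
#' Bundles everything [generate()] needs: sample size, the four risk-state
#' proportions, per-feature main-effect coefficients, pairwise
#' (order-2) interaction coefficients, noise level, and a seed. Effect
#' coefficients act on internally z-scored feature values so that a
#' coefficient of 1 means "one standard deviation of this feature moves the
#' latent risk score by 1", independent of the feature's raw units.
#'
#' The default class proportions follow a screening registry with a
#' low:medium:high:attack mix of 7221:5868:5475:1967 — about a 1:10
#' attack:non-attack imbalance.
#'
#' @param n_samples Number of rows to generate (at least 20).
#' @param class_proportions Nonnegative length-4 vector summing to 1
#'   (low, medium, high, attack).
#' @param main_effects Named numeric vector: feature -> coefficient.
#' @param pair_effects Named numeric vector: `"A|B"` -> coefficient, or a
#'   list of `list(features = c("A","B"), coef = x)`.
#' @param noise_scale Standard deviation of the additive Gaussian noise on
#'   the latent score.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_samples = 20531,
                           class_proportions = c(7221, 5868, 5475, 1967) / 20531,
                           main_effects = c(LSBP = 1, Exs = 0.8, Sm = 0.6,
                                            Wt = 0.5, TC = 0.5),
                           pair_effects = NULL,
                           noise_scale = 0.5,
                           seed = 1L) {
  stopifnot(length(class_proportions) == 4, all(class_proportions >= 0))
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1 (within 1e-9)", call. = FALSE)
  }
  pe <- normalize_pair_effects(pair_effects)
  structure(
    list(
      n_samples = as.integer(n_samples),
      class_proportions = as.numeric(class_proportions),
      main_effects = main_effects,
      pair_effects = pe,
      noise_scale = noise_scale,
      seed = as.integer(seed)
    ),
    class = "generator_spec"
  )
}

# accept either c("A|B" = 2) or list(list(features=c("A","B"), coef=2))
normalize_pair_effects <- function(pair_effects) {
  if (is.null(pair_effects) || length(pair_effects) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  if (is.list(pair_effects)) {
    keys <- purrr::map_chr(pair_effects, function(p) {
      pair_key(p$features[1], p$features[2])
    })
    pair_effects <- stats::setNames(
      purrr::map_dbl(pair_effects, "coef"), keys
    )
  }
  feats <- strsplit(names(pair_effects), "|", fixed = TRUE)
  keys <- purrr::map_chr(feats, function(f) {
    if (length(f) != 2 || f[1] == f[2]) {
      stop("pair effects need two distinct features", call. = FALSE)
    }
    pair_key(f[1], f[2])
  })
  stats::setNames(as.numeric(pair_effects), keys)
}

validate_spec <- function(spec, schema) {
  feats <- unique(c(
    names(spec$main_effects),
    unlist(strsplit(names(spec$pair_effects), "|", fixed = TRUE))
  ))
  missing <- setdiff(feats, schema$name)
  if (length(missing) > 0) {
    stop("effect features not in schema: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(spec)
}

#' Generate a synthetic labeled stroke-screening table
#'
#' Draws the 34 features of `schema` (categoricals from their code sets,
#' continuous features from normals truncated to their plausible range with
#' mean at the midpoint and sd = width/6; years of smoking is 0 for
#' never-smokers and uniform otherwise), builds a latent risk score
#' `sum(main effects) + sum(pair effects * x_i * x_j) + noise` on z-scored
#' feature values, and assigns the four risk states by the score's
#' empirical quantiles at `class_proportions`, so the realized class counts
#' match the requested proportions to within one sample. The binary
#' occurrence label is the indicator of the attack state.
#'
#' @param spec A [generator_spec()].
#' @param schema A schema tibble; defaults to [default_schema()].
#' @return A tibble with one column per schema feature plus integer columns
#'   `risk` (0 low, 1 medium, 2 high, 3 attack) and `occurrence` (0/1).
#'   The generating spec and schema are attached as attributes.
#' @examples
#' tab <- generate(generator_spec(n_samples = 200, seed = 7))
#' table(tab$risk)
#' @export
generate <- function(spec, schema = default_schema()) {
  stopifnot(inherits(spec, "generator_spec"))
  validate_spec(spec, schema)
  n <- spec$n_samples
  if (n < 20) stop("n_samples must be at least 20", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  cols <- vector("list", nrow(schema))
  names(cols) <- schema$name
  for (i in seq_len(nrow(schema))) {
    kind <- schema$kind[i]
    nm <- schema$name[i]
    if (nm == "Ys") {
      cols[[i]] <- rep(NA_real_, n) # filled after Sm is drawn
    } else if (kind == "continuous") {
      r <- schema$range[[i]]
      cols[[i]] <- rtruncnorm(n, mean(r), diff(r) / 6, r[1], r[2])
    } else {
      codes <- schema$codes[[i]]
      p <- categorical_probs(nm, codes)
      cols[[i]] <- as.numeric(sample(codes, n, replace = TRUE, prob = p))
    }
  }
  if ("Ys" %in% names(cols) && "Sm" %in% names(cols)) {
    r <- schema_feature(schema, "Ys")$range
    smoker <- cols[["Sm"]] > 0
    ys <- numeric(n)
    ys[smoker] <- runif(sum(smoker), r[1], r[2])
    cols[["Ys"]] <- ys
  }
  X <- tibble::as_tibble(cols)

  score <- latent_score(X, spec)
  risk <- assign_by_quantile(score, spec$class_proportions)

  out <- dplyr::mutate(
    X,
    risk = risk,
    occurrence = as.integer(risk == 3L)
  )
  attr(out, "spec") <- spec
  attr(out, "schema") <- schema
  class(out) <- c("labeled_table", class(out))
  out
}

# fixed plausible category frequencies (midpoint draw would be degenerate)
categorical_probs <- function(name, codes) {
  if (name == "Sm") return(c(0.55, 0.15, 0.30))
  if (length(codes) == 2) return(c(0.65, 0.35))
  rep(1 / length(codes), length(codes))
}

# z-score columns and combine main + pairwise effects + noise
latent_score <- function(X, spec) {
  n <- nrow(X)
  zs <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12) s <- 1
    (v - mean(v)) / s
  }
  score <- numeric(n)
  for (f in names(spec$main_effects)) {
    score <- score + spec$main_effects[[f]] * zs(X[[f]])
  }
  if (length(spec$pair_effects) > 0) {
    for (k in names(spec$pair_effects)) {
      f <- strsplit(k, "|", fixed = TRUE)[[1]]
      score <- score + spec$pair_effects[[k]] * zs(X[[f[1]]]) * zs(X[[f[2]]])
    }
  }
  if (spec$noise_scale > 0) score <- score + rnorm(n, 0, spec$noise_scale)
  score
}

# rank-based assignment: exact class counts from cumulative proportions
assign_by_quantile <- function(score, proportions) {
  n <- length(score)
  counts <- diff(c(0, round(cumsum(proportions) * n)))
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  rk <- rank(score, ties.method = "first")
  cls <- integer(n)
  bounds <- cumsum(counts)
  for (c in seq_along(counts)) {
    lo <- if (c == 1) 0 else bounds[c - 1]
    cls[rk > lo & rk <= bounds[c]] <- c - 1L
  }
  as.integer(cls)
}

#' Planted order-2 pairs of a generator spec
#'
#' Returns the feature pairs carrying nonzero interaction coefficients,
#' strongest first (ties broken by pair name) — the ground truth against
#' which interaction-screening recovery is judged.
#'
#' @param spec A [generator_spec()] with nonempty `pair_effects`.
#' @return A tibble with columns `feature1`, `feature2`, `coef`.
#' @export
planted_pairs <- function(spec) {
  pe <- spec$pair_effects[spec$pair_effects != 0]
  if (length(pe) == 0) {
    stop("spec has no planted pair effects", call. = FALSE)
  }
  feats <- strsplit(names(pe), "|", fixed = TRUE)
  out <- tibble::tibble(
    feature1 = purrr::map_chr(feats, 1),
    feature2 = purrr::map_chr(feats, 2),
    coef = as.numeric(pe)
  )
  dplyr::arrange(out, dplyr::desc(abs(.data$coef)),
                 .data$feature1, .data$feature2)
}

#' Write / read a labeled table as CSV
#'
#' The CSV carries one column per schema feature plus `risk` and
#' `occurrence`, in schema order.
#'
#' @param table A labeled table from [generate()] (or compatible tibble).
#' @param path File path.
#' @param schema Schema used to restore column order and check names.
#' @return `read_labeled_csv()` returns the tibble; `write_labeled_csv()`
#'   returns `path` invisibly.
#' @export
write_labeled_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labeled_csv
#' @export
read_labeled_csv <- function(path, schema = default_schema()) {
  df <- read.csv(path, check.names = FALSE)
  missing <- setdiff(c(schema$name, "risk", "occurrence"), names(df))
  if (length(missing) > 0) {
    stop("CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(df)[, c(schema$name, "risk", "occurrence")]
  attr(out, "schema") <- schema
  class(out) <- c("labeled_table", class(out))
  out
}

# save/restore global RNG state so seeded helpers don't clobber callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
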