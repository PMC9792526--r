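#' Confusion matrix
#'
#' @param true Integer true labels in `[0, n_classes)`.
#' @param pred Integer predicted labels in `[0, n_classes)`.
#' @param n_classes Number of classes (default 4).
#' @return An `n_classes x n_classes` integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion <- function(true, pred, n_classes = 4) {
  stopifnot(length(true) == length(pred))
  if (any(true < 0 | true >= n_classes) ||
      any(pred < 0 | pred >= n_classes)) {
    stop("labels out of range", call. = FALSE)
  }
  cm <- table(factor(true, levels = 0:(n_classes - 1)),
              factor(pred, levels = 0:(n_classes - 1)))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(true = rownames(cm), pred = colnames(cm)))
  cm
}

#' Precision, recall and F1 of one class
#'
#' Returns the three scores as percentages; a zero denominator yields 0
#' (flagged by the `degenerate` field).
#'
#' @param cm Confusion matrix from [confusion()].
#' @param class 0-based class index.
#' @return Tibble with `precision`, `recall`, `f1` (in %), `support`,
#'   `degenerate`.
#' @export
prf1 <- function(cm, class) {
  i <- class + 1L
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  tibble::tibble(
    class = class, precision = 100 * prec, recall = 100 * rec,
    f1 = 100 * f1, support = sum(cm[i, ]),
    degenerate = (tp + fp == 0) || (tp + fn == 0)
  )
}

#' F1 from precision and recall percentages
#'
#' Harmonic mean of precision and recall, all in percent.
#'
#' @param precision,recall Percentages.
#' @return F1 in percent.
#' @examples
#' f1_score(100, 53.42) # 69.64
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Full classification report
#'
#' Per-class precision/recall/F1 plus the unweighted macro means and the
#' overall accuracy — the evaluation surface used for the four risk
#' states.
#'
#' @param true,pred Integer label vectors.
#' @param n_classes Number of classes (default 4).
#' @param class_names Optional names (default the four risk states when
#'   `n_classes == 4`).
#' @return A `metrics_report` tibble (one row per class) with attributes
#'   `accuracy`, `macro` (named vector: precision, recall, f1) and
#'   `confusion`.
#' @export
metrics_report <- function(true, pred, n_classes = 4,
                           class_names = NULL) {
  cm <- confusion(true, pred, n_classes)
  rows <- dplyr::bind_rows(
    purrr::map(0:(n_classes - 1), ~ prf1(cm, .x))
  )
  class_names <- class_names %||%
    if (n_classes == 4) risk_levels else paste0("class", 1:n_classes)
  rows <- dplyr::mutate(rows, state = class_names, .after = "class")
  attr(rows, "accuracy") <- accuracy(cm)
  attr(rows, "macro") <- c(
    precision = mean(rows$precision),
    recall = mean(rows$recall),
    f1 = mean(rows$f1)
  )
  attr(rows, "confusion") <- cm
  class(rows) <- c("metrics_report", class(rows))
  rows
}

#' Macro means of a classification report
#'
#' @param report A `metrics_report`.
#' @return Named numeric vector: mean precision, recall and F1 over all
#'   classes (unweighted), in percent.
#' @export
macro <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  attr(report, "macro")
}

#' Accuracy of a confusion matrix
#'
#' @param cm Confusion matrix.
#' @return Accuracy in percent.
#' @export
accuracy <- function(cm) {
  100 * sum(diag(cm)) / sum(cm)
}

#' Area under the ROC curve (rank formulation)
#'
#' The probability that a randomly chosen positive scores above a
#' randomly chosen negative, ties counted one-half — computed from
#' midranks, equivalent to normalized pairwise counting but O(n log n).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Relative and absolute change between two metric values
#'
#' `percent_change()` is the relative change `100 * (new - old) / old`
#' (e.g. a recall moving 84.75 -> 89.56 is a 5.68% relative increase);
#' `point_change()` is the absolute percentage-point difference
#' `new - old`. Reports should state which convention they use.
#'
#' @param old,new Metric values; `old` must be positive for
#'   `percent_change()`.
#' @return A single number.
#' @export
percent_change <- function(old, new) {
  if (any(old <= 0)) stop("old value must be positive", call. = FALSE)
  100 * (new - old) / old
}

#' @rdname percent_change
#' @export
point_change <- function(old, new) {
  new - old
}

#' Aggregate metric reports over repeated runs
#'
#' Per metric: mean, sample standard deviation and the 95% normal
#' confidence interval `mean +/- 1.96 * sd / sqrt(runs)`.
#'
#' @param runs A list of `metrics_report`s (>= 2) from repeated
#'   train/evaluate runs, or a numeric vector of a single metric.
#' @return Tibble with `state`, `metric`, `mean`, `sd`, `ci_lo`, `ci_hi`,
#'   `n_runs`. For a numeric vector input, a single-row tibble.
#' @export
aggregate_runs <- function(runs) {
  if (is.numeric(runs)) {
    if (length(runs) < 2) stop("need at least 2 runs", call. = FALSE)
    return(summarise_metric(runs, state = "all", metric = "value"))
  }
  stopifnot(is.list(runs), length(runs) >= 2)
  long <- purrr::imap(runs, function(rep, i) {
    out <- tidyr::pivot_longer(
      dplyr::select(tibble::as_tibble(rep), "state", "precision",
                    "recall", "f1"),
      cols = c("precision", "recall", "f1"),
      names_to = "metric", values_to = "value"
    )
    acc <- tibble::tibble(state = "all", metric = "accuracy",
                          value = attr(rep, "accuracy"))
    mac <- tibble::tibble(
      state = "all",
      metric = paste0("macro_", names(attr(rep, "macro"))),
      value = as.numeric(attr(rep, "macro"))
    )
    dplyr::bind_rows(out, acc, mac)
  })
  dplyr::bind_rows(long) |>
    dplyr::group_by(.data$state, .data$metric) |>
    dplyr::summarise(
      summarise_metric(.data$value)[, c("mean", "sd", "ci_lo", "ci_hi",
                                        "n_runs")],
      .groups = "drop"
    )
}

summarise_metric <- function(x, state = NULL, metric = NULL) {
  m <- mean(x)
  s <- stats::sd(x)
  hw <- 1.96 * s / sqrt(length(x))
  out <- tibble::tibble(mean = m, sd = s, ci_lo = m - hw, ci_hi = m + hw,
                        n_runs = length(x))
  if (!is.null(state)) out <- dplyr::mutate(out, state = state,
                                            metric = metric, .before = 1)
  out
}
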