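# Top-N evaluation framework: top-N accuracies, the frequency and balanced
# (random) reference baselines, 1/N-scaled per-class precision/recall,
# k-fold cross-validation and permutation feature importance.

.as_prediction_matrix <- function(predictions) {
  if (is.list(predictions)) {
    len <- unique(lengths(predictions))
    if (length(len) != 1L) stop("all prediction lists must have equal length")
    predictions <- do.call(rbind, predictions)
  }
  if (!is.matrix(predictions)) predictions <- matrix(predictions, ncol = 1)
  predictions
}

#' Top-N accuracy
#'
#' Percentage of examples whose true label appears in their ordered top-N
#' prediction list.
#'
#' @param truths integer vector of true space-group labels.
#' @param predictions integer matrix (one row per example, N columns), or a
#'   list of equal-length integer vectors.
#' @return Accuracy in percent.
#' @export
top_n_accuracy <- function(truths, predictions) {
  P <- .as_prediction_matrix(predictions)
  if (nrow(P) != length(truths)) {
    stop("predictions (", nrow(P), ") do not align with truths (",
         length(truths), ")")
  }
  100 * mean(vapply(seq_along(truths),
                    function(i) truths[i] %in% P[i, ], TRUE))
}

#' Frequency reference accuracy
#'
#' Accuracy obtained by always predicting the N most frequent space groups:
#' the proportion of the test truths covered by the first `n` entries of
#' `frequency_order`.
#'
#' @param truths integer test labels.
#' @param frequency_order integer vector of space-group numbers in
#'   decreasing frequency order (typically computed from the training split,
#'   standing in for database-wide frequencies; a user-supplied order may be
#'   passed instead).
#' @param n number of predicted groups.
#' @return Accuracy in percent.
#' @export
reference_accuracy_frequency <- function(truths, frequency_order, n) {
  if (!all(unique(truths) %in% frequency_order)) {
    stop("frequency_order must cover all test labels")
  }
  if (n < 1 || n > length(frequency_order)) {
    stop("n must lie in 1..", length(frequency_order))
  }
  100 * mean(truths %in% frequency_order[seq_len(n)])
}

#' Balanced (random) reference accuracy
#'
#' For a balanced dataset over `m_classes` space groups, random guessing of
#' N groups yields `100 * n / m_classes` percent.
#'
#' @param m_classes number of space groups in the balanced dataset.
#' @param n number of predicted groups (1 <= n <= m_classes).
#' @return Accuracy in percent.
#' @export
reference_accuracy_balanced <- function(m_classes, n) {
  if (n < 1 || n > m_classes) stop("n must lie in 1..", m_classes)
  100 * n / m_classes
}

#' 1/N-scaled per-class precision and recall
#'
#' Per example: if the true label is in the top-N list, its class gains
#' `tp += 1`; otherwise it gains `fn += 1`. Every other listed class gains
#' `fp += 1/N` (the 1/N scaling keeps false positives from exploding with
#' N). Classes never predicted (`tp + fp = 0`) get `NA` precision rather
#' than zero.
#'
#' @param truths integer test labels.
#' @param predictions top-N lists (matrix or list, as in
#'   [top_n_accuracy()]).
#' @return data.frame with one row per class: `class`, `tp`, `fp`, `fn`,
#'   `recall`, `precision`.
#' @export
scaled_precision_recall <- function(truths, predictions) {
  P <- .as_prediction_matrix(predictions)
  stopifnot(nrow(P) == length(truths))
  n <- ncol(P)
  classes <- sort(unique(c(truths, as.integer(P))))
  z <- stats::setNames(numeric(length(classes)), classes)
  tp <- z; fp <- z; fn <- z
  for (i in seq_along(truths)) {
    g <- as.character(truths[i])
    listed <- as.character(P[i, ])
    if (truths[i] %in% P[i, ]) {
      tp[g] <- tp[g] + 1
      others <- setdiff(listed, g)
    } else {
      fn[g] <- fn[g] + 1
      others <- listed
    }
    if (length(others)) fp[others] <- fp[others] + 1 / n
  }
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  data.frame(class = classes, tp = as.numeric(tp), fp = as.numeric(fp),
             fn = as.numeric(fn), recall = as.numeric(recall),
             precision = as.numeric(precision), row.names = NULL)
}

#' Assemble the full evaluation report
#'
#' @param probs per-class probability matrix (rows = test examples, columns
#'   named by space-group number), e.g. from [predict.xtal_forest()] or
#'   [predict_gnn()].
#' @param truths integer test labels aligned with the rows.
#' @param n_set top-N values to evaluate (default 1, 3, 5, 10; values
#'   exceeding the class count are dropped).
#' @param reference `"frequency"` (uneven datasets; needs
#'   `frequency_order`) or `"balanced"` (random reference `100 * n / m`).
#' @param frequency_order decreasing-frequency space-group order for the
#'   frequency reference.
#' @param m_classes class count for the balanced reference (default: number
#'   of probability columns).
#' @param train_freq optional named training-frequency table for prediction
#'   tie-breaks.
#' @return Object of class `xtal_eval`: per-N accuracies, references,
#'   deltas, per-class scaled precision/recall tables, and `n_test`.
#' @export
evaluate_predictions <- function(probs, truths,
                                 n_set = c(1, 3, 5, 10),
                                 reference = c("frequency", "balanced"),
                                 frequency_order = NULL, m_classes = NULL,
                                 train_freq = NULL) {
  reference <- match.arg(reference)
  if (length(truths) == 0L) stop("empty test set")
  stopifnot(is.matrix(probs), nrow(probs) == length(truths))
  k <- ncol(probs)
  n_set <- sort(unique(n_set[n_set >= 1 & n_set <= k]))
  if (reference == "frequency" && is.null(frequency_order)) {
    stop("the frequency reference needs `frequency_order`")
  }
  if (is.null(m_classes)) m_classes <- k

  out <- list()
  per_class <- list()
  for (n in n_set) {
    top <- top_n_classes(probs, n, train_freq)
    if (n == 1L) top <- matrix(top, ncol = 1)
    acc <- top_n_accuracy(truths, top)
    ref <- if (reference == "frequency") {
      reference_accuracy_frequency(truths, frequency_order, n)
    } else {
      reference_accuracy_balanced(m_classes, n)
    }
    out[[length(out) + 1L]] <- data.frame(n = n, accuracy = acc,
                                          reference = ref, delta = acc - ref)
    per_class[[as.character(n)]] <- scaled_precision_recall(truths, top)
  }
  structure(list(summary = do.call(rbind, out),
                 per_class = per_class,
                 reference = reference,
                 n_test = length(truths)),
            class = "xtal_eval")
}

#' @export
print.xtal_eval <- function(x, ...) {
  cat(sprintf("<xtal_eval: %d test molecules, %s reference>\n", x$n_test,
              x$reference))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  top-%-2d acc %6.2f%%  ref %6.2f%%  delta %+6.2f%%\n",
                s$n[i], s$accuracy[i], s$reference[i], s$delta[i]))
  }
  invisible(x)
}

#' Write / read an evaluation report (JSON)
#'
#' @param report an `xtal_eval` object.
#' @param path JSON file path.
#' @return `write_eval_report`: the path, invisibly. `read_eval_report`: the
#'   restored `xtal_eval` object.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "xtal_eval"))
  jsonlite::write_json(list(summary = report$summary,
                            per_class = report$per_class,
                            reference = report$reference,
                            n_test = report$n_test),
                       path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(summary = as.data.frame(x$summary),
                 per_class = lapply(x$per_class, as.data.frame),
                 reference = x$reference,
                 n_test = as.integer(x$n_test)),
            class = "xtal_eval")
}

#' k-fold cross-validation
#'
#' Splits the feature table into `k` seeded disjoint folds; each fold is
#' held out in turn, a model is trained on the rest and top-N accuracies
#' plus frequency-reference deltas are computed on the held-out fold (the
#' frequency order is taken from each training portion). A warning is given
#' when a class is absent from a training portion (the class stays in the
#' label space).
#'
#' @param table an `xtal_features` table.
#' @param labels integer labels aligned with the rows.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the fold assignment and trainers.
#' @param n_set top-N values (default 1, 3, 5, 10).
#' @param trainer function(table, labels, seed) returning a model accepted
#'   by [stats::predict()]; default trains the random forest.
#' @return List with `folds` (per-fold data.frame of accuracies and deltas),
#'   `mean` and `sd` (per-N summaries across folds).
#' @export
cross_validate <- function(table, labels, k = 10L, seed = 1L,
                           n_set = c(1, 3, 5, 10), trainer = NULL) {
  stopifnot(inherits(table, "xtal_features"), k >= 2,
            nrow(table$values) >= k)
  labels <- as.integer(labels)
  if (is.null(trainer)) {
    trainer <- function(tbl, labs, s) train_forest(tbl, labs, seed = s)
  }
  n <- nrow(table$values)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  res <- list()
  for (f in seq_len(k)) {
    tr <- fold != f
    missing_cls <- setdiff(unique(labels), unique(labels[tr]))
    if (length(missing_cls)) {
      warning("fold ", f, ": class(es) ", paste(missing_cls, collapse = ", "),
              " absent from the training portion")
    }
    sub <- function(idx) .new_feature_table(
      table$values[idx, , drop = FALSE], table$column_class,
      table$geometry_source, table$selection)
    model <- trainer(sub(tr), labels[tr], seed + f)
    probs <- predict(model, sub(!tr))
    freq_order <- as.integer(names(sort(table(labels[tr]), decreasing = TRUE)))
    freq_order <- c(freq_order, setdiff(sort(unique(labels)), freq_order))
    for (nn in n_set[n_set <= ncol(probs)]) {
      top <- top_n_classes(probs, nn)
      if (nn == 1L) top <- matrix(top, ncol = 1)
      acc <- top_n_accuracy(labels[!tr], top)
      ref <- reference_accuracy_frequency(labels[!tr], freq_order, nn)
      res[[length(res) + 1L]] <- data.frame(fold = f, n = nn, accuracy = acc,
                                            reference = ref,
                                            delta = acc - ref,
                                            n_test = sum(!tr))
    }
  }
  folds <- do.call(rbind, res)
  agg <- function(fun) stats::aggregate(cbind(accuracy, reference, delta) ~ n,
                                        folds, fun)
  list(folds = folds, mean = agg(mean), sd = agg(stats::sd))
}

#' Permutation feature importance
#'
#' For each feature column, the held-out top-1 accuracy is recomputed
#' `n_repeats` times with that column's values shuffled (seeded); the
#' importance is the baseline accuracy minus the mean shuffled accuracy.
#'
#' @param model trained model accepted by [stats::predict()].
#' @param table held-out `xtal_features` table.
#' @param labels integer labels aligned with the rows.
#' @param n_repeats shuffles per feature (>= 1).
#' @param seed integer seed.
#' @return data.frame: `feature`, `importance` (percentage-point accuracy
#'   drop), `sd` over repeats, and the shared `baseline` accuracy.
#' @export
permutation_importance <- function(model, table, labels, n_repeats = 5L,
                                   seed = 1L) {
  stopifnot(inherits(table, "xtal_features"))
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  labels <- as.integer(labels)
  top1_acc <- function(tbl) {
    probs <- predict(model, tbl)
    top_n_accuracy(labels, matrix(top_n_classes(probs, 1L), ncol = 1))
  }
  baseline <- top1_acc(table)
  set.seed(seed)
  out <- list()
  for (cn in colnames(table$values)) {
    drops <- numeric(n_repeats)
    for (rps in seq_len(n_repeats)) {
      V <- table$values
      V[, cn] <- sample(V[, cn])
      tbl <- .new_feature_table(V, table$column_class,
                                table$geometry_source, table$selection)
      drops[rps] <- baseline - top1_acc(tbl)
    }
    out[[length(out) + 1L]] <- data.frame(feature = cn,
                                          importance = mean(drops),
                                          sd = stats::sd(drops))
  }
  res <- do.call(rbind, out)
  res$baseline <- baseline
  res[order(-res$importance), ]
}

#' Evaluate a trained model on a held-out record set
#'
#' Convenience wrapper: computes class probabilities and assembles the full
#' report via [evaluate_predictions()].
#'
#' @param model trained model accepted by [stats::predict()].
#' @param table held-out `xtal_features` table.
#' @param labels integer labels aligned with the rows.
#' @inheritParams evaluate_predictions
#' @return An `xtal_eval` report.
#' @export
evaluate_model <- function(model, table, labels, n_set = c(1, 3, 5, 10),
                           reference = c("frequency", "balanced"),
                           frequency_order = NULL, m_classes = NULL) {
  probs <- predict(model, table)
  tf <- if (inherits(model, "xtal_forest")) model$train_freq else NULL
  evaluate_predictions(probs, as.integer(labels), n_set = n_set,
                       reference = reference,
                       frequency_order = frequency_order,
                       m_classes = m_classes, train_freq = tf)
}
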